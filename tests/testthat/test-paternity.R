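test_that("infer_paternal_allele attributes the non-maternal base", {
  expect_identical(infer_paternal_allele("A/G", "A"), "G")
  expect_identical(infer_paternal_allele("A/A", "A"), "A")
  expect_identical(infer_paternal_allele("G/G", "A"), "mismatch")
  expect_identical(infer_paternal_allele(NA, "A"), NA_character_)
  # vectorized over markers with differing maternal bases
  expect_identical(infer_paternal_allele(c("A/G", "C/T", NA), c("A", "T", "G")),
                   c("G", "C", NA))
})

sig4 <- rbind(F1 = c("A", "A", "A", "A"),
              F2 = c("G", "G", "A", "A"),
              F3 = c("A", "G", "G", "A"))
colnames(sig4) <- paste0("m", 1:4)

test_that("match_father implements the 0/1/2-ignore union rule", {
  r <- match_father(c(A = "A", B = "A", C = "A", D = "A"), sig4)
  expect_identical(r$status, "assigned")
  expect_identical(r$father, "F1")
  expect_identical(r$n_ignored, 0L)
  # ambiguity: ignoring m1 matches F1, ignoring m2 matches F2
  r <- match_father(c("G", "A", "A", "A"), sig4)
  expect_identical(r$status, "ambiguous")
  # a missing position consumes the single-ignore budget
  r <- match_father(c("G", "G", "A", NA), sig4)
  expect_identical(r$status, "assigned")
  expect_identical(r$father, "F2")
  expect_identical(r$n_ignored, 1L)
  expect_identical(r$ignored_markers, "m4")
  # more missing than budget
  r <- match_father(c("G", NA, NA, NA), sig4, max_ignored = 2)
  expect_identical(r$status, "unassigned")
})

test_that("match_father agrees with explicit ignore-subset enumeration", {
  set.seed(42)
  for (rep in 1:300) {
    pat <- sample(c("A", "G", NA), 4, replace = TRUE,
                  prob = c(0.45, 0.45, 0.1))
    got <- match_father(pat, sig4)
    want <- oracle_match(pat, sig4)
    expect_identical(got$status, want$status,
                     label = paste(c("vec:", ifelse(is.na(pat), ".", pat)),
                                   collapse = ""))
    if (want$status == "assigned") {
      expect_identical(got$father, want$father)
      expect_identical(got$n_ignored, as.integer(want$n_ignored))
    }
  }
})

test_that("raising max_ignored never unassigns and levels stop at first decision", {
  set.seed(7)
  sig <- random_hom_panel(6, 6, seed = 3)$sig
  for (rep in 1:150) {
    pat <- sample(c("A", "G", NA), 6, replace = TRUE, prob = c(.45, .45, .1))
    r1 <- match_father(pat, sig, max_ignored = 1)
    r2 <- match_father(pat, sig, max_ignored = 2)
    if (r1$status == "assigned") {
      expect_identical(r2$status, "assigned")
      expect_identical(r2$father, r1$father)
      expect_identical(r2$n_ignored, r1$n_ignored)
    }
  }
})

test_that("assign_batch recovers all fathers on noise-free data", {
  s <- sim_batch(21)
  ab <- assign_batch(s$calls, s$panel)
  expect_true(all(ab$assignments$status == "assigned"))
  expect_true(all(ab$assignments$n_ignored == 0L))
  expect_identical(ab$assignments$father_genotype, s$truth$donor_genotype)
  expect_true(all(ab$summary$identification_rate == 1))
})

test_that("assign_batch under call noise stays accurate and resamples mismatches", {
  s <- sim_batch(22, noise = noise_model(0.02, 0.01))
  ab <- assign_batch(s$calls, s$panel)
  a <- ab$assignments
  ok <- a$status == "assigned"
  # >= 99% of assigned fathers agree with the simulator truth
  expect_gt(mean(a$father_genotype[ok] == s$truth$donor_genotype[ok]), 0.99)
  expect_gt(sum(ab$summary$assigned) / sum(ab$summary$sampled), 0.9)
  # resampling with clean second calls rescues maternal mismatches
  clean <- genotype_offspring(s$truth, s$panel, noise_model(0, 0),
                              rng_seed = 77)
  ab2 <- assign_batch(s$calls, s$panel, resample_table = clean)
  expect_identical(sum(ab2$assignments$status == "maternal_mismatch"), 0L)
  n_mm <- sum(a$status == "maternal_mismatch")
  expect_gt(n_mm, 0)  # the noisy batch did trigger the rule
  # without a resample entry the seed stays omitted
  expect_true(all(a$status[a$status == "maternal_mismatch"] ==
                    "maternal_mismatch"))
})

test_that("assign_batch edge cases", {
  s <- sim_batch(23, n_blocks = 1, seeds_per_plant = 1)
  empty <- s$calls[0, ]
  ab <- assign_batch(empty, s$panel)
  expect_equal(nrow(ab$assignments), 0)
  expect_equal(nrow(ab$summary), 0)
  bad <- s$calls[1, ]
  bad$mother_genotype <- "nope"
  expect_error(assign_batch(bad, s$panel), "not in panel")
})

test_that("classify_seed partitions assigned seeds", {
  expect_identical(classify_seed("G1", "G1"), "self_or_intra")
  expect_identical(classify_seed("G2", "G1"), "inter")
  expect_error(classify_seed("G2", "G1", status = "unassigned"), "assigned")
  s <- sim_batch(24)
  ab <- assign_batch(s$calls, s$panel)
  cls <- classify_seed(ab$assignments$father_genotype,
                       ab$assignments$mother_genotype)
  expect_equal(sum(cls == "self_or_intra") + sum(cls == "inter"),
               sum(ab$assignments$status == "assigned"))
})

test_that("confirm_f1_hybrid checks heterozygosity at informative markers", {
  p <- make_default_panel()
  expect_true(confirm_f1_hybrid(p, "G7"))
  expect_true(confirm_f1_hybrid(p, "G8"))
  # a selfed 'F1' (homozygous at the confirmation markers) fails
  p2 <- p
  p2$calls["G7", c("c1", "c2")] <- "A/A"
  expect_false(confirm_f1_hybrid(p2, "G7"))
  # parents sharing an allele make the marker uninformative
  p3 <- p
  p3$calls["L2", "c1"] <- "A/A"
  expect_error(confirm_f1_hybrid(p3, "G7"), "same allele")
})
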