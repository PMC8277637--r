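test_that("build_c_dataset aggregates assigned seeds per MG x block", {
  asg <- data.frame(
    seed_id = sprintf("S%03d", 1:10),
    mother_genotype = c(rep("G1", 6), rep("G2", 4)),
    block = c(1, 1, 1, 2, 2, 2, 1, 1, 2, 2), year = 1,
    status = c(rep("assigned", 9), "unassigned"),
    father_genotype = c("G2", "G1", "G1", "G2", "G2", "G1",
                        "G1", "G2", "G2", "G1"))
  cd <- build_c_dataset(asg)
  expect_equal(nrow(cd), 4)
  g1b1 <- cd[cd$maternal_genotype == "G1" & cd$block == 1, ]
  expect_equal(g1b1$n_cross, 1)   # one inter (father G2)
  expect_equal(g1b1$n_self, 2)
  # conservation: totals equal the number of assigned seeds
  expect_equal(sum(cd$n_cross + cd$n_self), 9)
  # empty cells carry (0, 0)
  cd2 <- build_c_dataset(asg, genotypes = c("G1", "G2", "G3"))
  g3 <- cd2[cd2$maternal_genotype == "G3", ]
  expect_true(all(g3$n_cross == 0 & g3$n_self == 0))
})

test_that("intra-genotype imputation yields an exact 1/8 diagonal share", {
  r <- impute_intra_genotype(rep(7, 7))
  expect_equal(r$diagonal, 7)
  expect_equal(r$total, 56)
  expect_equal(r$diagonal_share, 1 / 8)
  expect_equal(impute_intra_genotype(rep(0, 7))$diagonal, 0)
  r2 <- impute_intra_genotype(1:7)
  expect_equal(r2$diagonal, 4)
  expect_equal(r2$total, 32)
  expect_equal(r2$diagonal_share, 1 / 8)
  # arbitrary counts: the identity is algebraic
  set.seed(1)
  for (i in 1:20) {
    cnt <- rpois(7, lambda = sample(1:30, 1))
    r <- impute_intra_genotype(cnt)
    if (r$total > 0) expect_equal(r$diagonal_share, 1 / 8)
    expect_equal(r$total, sum(cnt) * 8 / 7)
  }
})

test_that("pair counts and the P dataset respect the imputation identities", {
  s <- sim_batch(31)
  ab <- assign_batch(s$calls, s$panel)
  pc <- build_pair_counts(ab$assignments)
  expect_equal(nrow(pc), 512)
  diag_rows <- pc$maternal_genotype == pc$paternal_genotype
  expect_true(all(pc$seeds_sired[!diag_rows] == round(pc$seeds_sired[!diag_rows])))
  # diagonal = mean of the seven off-diagonal entries of its cell
  cell <- paste(pc$maternal_genotype, pc$block)
  for (cl in unique(cell[diag_rows])[1:5]) {
    d <- pc$seeds_sired[diag_rows & cell == cl]
    o <- pc$seeds_sired[!diag_rows & cell == cl]
    expect_equal(d, mean(o))
  }
  pd <- build_p_dataset(pc)
  expect_equal(nrow(pd), 512)
  # successes sum to the cell total within each MG cell
  tot <- tapply(pd$n_cross_pg, cell, sum)
  first <- tapply(pd$n_cross_pg + pd$n_cross_other, cell, function(x) x[1])
  expect_equal(unname(tot), unname(first))
  # diagonal share of each cell total is exactly 1/8
  dshare <- pd$n_cross_pg[diag_rows] /
    (pd$n_cross_pg + pd$n_cross_other)[diag_rows]
  expect_equal(dshare, rep(1 / 8, sum(diag_rows)))
})

test_that("fit_binomial_glm matches saturated/pooled closed forms", {
  dat <- data.frame(g = c("a", "b"), k = c(30, 70), f = c(70, 30))
  fit <- fit_binomial_glm(dat, "k", "f", "g")
  mu <- fit$fit$linear.predictors
  expect_equal(unname(mu), c(log(30 / 70), log(70 / 30)), tolerance = 1e-8)
  expect_equal(fit$fit$deviance, 0, tolerance = 1e-10)
  # intercept-only pools the proportions
  dat2 <- data.frame(g = "a", k = c(10, 20, 30), f = c(30, 20, 10))
  fit2 <- fit_binomial_glm(dat2, "k", "f", "1")
  expect_equal(unname(fit2$fit$fitted.values[1]), 0.5, tolerance = 1e-10)
})

test_that("GLM coefficients match the independent IRLS oracle to 1e-6", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 48
    dat <- data.frame(g = factor(sample(letters[1:4], n, TRUE)),
                      b = factor(sample(1:3, n, TRUE)))
    tot <- rpois(n, 40) + 5
    eta <- -0.4 + 0.5 * as.integer(dat$g) - 0.2 * as.integer(dat$b)
    dat$k <- rbinom(n, tot, 1 / (1 + exp(-eta)))
    dat$f <- tot - dat$k
    fit <- fit_binomial_glm(dat, "k", "f", c("g", "b"))
    X <- model.matrix(~ g + b, dat)
    beta <- oracle_irls(X, dat$k, tot)
    expect_equal(unname(coef(fit$fit)), unname(beta), tolerance = 1e-6)
  }
  # fractional (imputed) successes run through the same weighted IRLS
  dat$k <- dat$k + 1 / 7
  fit <- fit_binomial_glm(dat, "k", "f", c("g", "b"))
  beta <- oracle_irls(model.matrix(~ g + b, dat), dat$k, dat$k + dat$f)
  expect_equal(unname(coef(fit$fit)), unname(beta), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("deviance_table is sequential, additive, and has the design dfs", {
  s <- sim_batch(32)
  ab <- assign_batch(s$calls, s$panel)
  cd <- build_c_dataset(ab$assignments)
  cfit <- fit_binomial_glm(cd, "n_cross", "n_self",
                           c("maternal_genotype", "block"))
  tab <- deviance_table(cfit)
  expect_identical(tab$term,
                   c("Null", "maternal_genotype", "block", "Residual"))
  expect_equal(tab$df, c(63, 7, 7, 49))
  # additivity of the sequential decomposition
  expect_equal(tab$deviance[1], sum(tab$deviance[-1]), tolerance = 1e-8)
  pd <- build_p_dataset(build_pair_counts(ab$assignments))
  pfit <- fit_binomial_glm(pd, "n_cross_pg", "n_cross_other",
                           c("paternal_genotype", "maternal_genotype",
                             "paternal_genotype:maternal_genotype", "block"))
  ptab <- deviance_table(pfit)
  expect_equal(ptab$df, c(511, 7, 7, 49, 7, 441))
  expect_equal(ptab$deviance[1], sum(ptab$deviance[-1]), tolerance = 1e-8)
  # P response construction kills MG and block main effects (noise-free data)
  s0 <- sim_batch(33)
  ab0 <- assign_batch(s0$calls, s0$panel)
  pd0 <- build_p_dataset(build_pair_counts(ab0$assignments))
  pfit0 <- fit_binomial_glm(pd0, "n_cross_pg", "n_cross_other",
                            c("paternal_genotype", "maternal_genotype",
                              "paternal_genotype:maternal_genotype", "block"))
  ptab0 <- deviance_table(pfit0)
  expect_lt(ptab0$deviance[ptab0$term == "maternal_genotype"], 1e-6)
  expect_lt(ptab0$deviance[ptab0$term == "block"], 1e-6)
})

test_that("ls_means equal observed logits on balanced one-factor data and brute-force averages on grids", {
  dat <- data.frame(g = rep(c("a", "b"), each = 2),
                    k = c(12, 18, 40, 20), f = c(28, 22, 20, 40))
  fit <- fit_binomial_glm(dat, "k", "f", "g")
  lsm <- ls_means(fit, "g")
  expect_equal(lsm$logit_mean, c(log(30 / 50), log(60 / 60)), tolerance = 1e-8)
  expect_equal(inv_val <- lsm$mean, c(0.375, 0.5), tolerance = 1e-8)
  # back-transform of logit 0 is 0.5 (level b above)
  # equal-weight marginalization equals the brute-force prediction average
  set.seed(5)
  dat2 <- expand.grid(g = letters[1:3], b = LETTERS[1:4],
                      stringsAsFactors = TRUE)
  tot <- rpois(12, 50) + 10
  dat2$k <- rbinom(12, tot, 0.4)
  dat2$f <- tot - dat2$k
  fit2 <- fit_binomial_glm(dat2, "k", "f", c("g", "b"))
  lsm2 <- ls_means(fit2, "g")
  eta <- predict(fit2$fit, newdata = dat2, type = "link")
  brute <- tapply(eta, dat2$g, mean)
  expect_equal(lsm2$logit_mean, as.numeric(brute), tolerance = 1e-10)
})

test_that("Bonferroni contrasts and compact letters behave", {
  # adjusted p values are min(1, m p)
  dat <- data.frame(g = c("a", "b", "c"), k = c(10, 50, 90),
                    f = c(90, 50, 10))
  fit <- fit_binomial_glm(dat, "k", "f", "g")
  lsm <- ls_means(fit, "g")
  con <- lsmean_contrasts(lsm)
  expect_equal(con$contrasts$m, rep(3, 3))
  expect_equal(con$contrasts$p_adjusted,
               pmin(1, 3 * con$contrasts$p_value))
  # all pairwise significant -> all letters distinct
  expect_equal(length(unique(con$letters)), 3)
  # group contrast enters the family
  con2 <- lsmean_contrasts(lsm, groups = list(lo = "a", hi = c("b", "c")))
  expect_equal(con2$contrasts$m[1], 4)
  expect_identical(con2$contrasts$contrast[1], "lo - hi")
})

test_that("compact_letters matches the clique-based sharing oracle", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(3:7, 1)
    sig <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      sig[i, j] <- sig[j, i] <- runif(1) < 0.4
    lt <- compact_letters(sig)
    share <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
      any(strsplit(lt[i], "")[[1]] %in% strsplit(lt[j], "")[[1]])))
    want <- oracle_cld_share(sig)
    expect_identical(unname(share), unname(want), label = paste("rep", rep))
  }
})

test_that("estimate_p: shares sum to one, diagonal 1/8, weight ranking recovered", {
  s <- sim_batch(35, w = 1:8)
  ab <- assign_batch(s$calls, s$panel)
  pc <- build_pair_counts(ab$assignments)
  cell <- paste(pc$maternal_genotype, pc$block)
  pd <- build_p_dataset(pc)
  # per-cell shares of the 8 donors sum to 1
  sh <- pd$n_cross_pg / (pd$n_cross_pg + pd$n_cross_other)
  expect_equal(as.numeric(tapply(sh, cell, sum)), rep(1, 64),
               tolerance = 1e-12)
  # the raw mean P is exactly 12.5% on the share scale
  expect_equal(mean(tapply(sh, paste(pd$paternal_genotype), mean)), 1 / 8,
               tolerance = 1e-12)
  pfit <- fit_binomial_glm(pd, "n_cross_pg", "n_cross_other",
                           c("paternal_genotype", "maternal_genotype",
                             "paternal_genotype:maternal_genotype", "block"))
  pl <- estimate_p(pfit)
  # GLM-smoothed mean stays within 0.7 percentage points of 12.5%
  expect_lt(abs(mean(pl$mean) - 0.125), 0.007)
  # estimated P tracks the true donor weights (w = 1..8): near-perfect rank
  # agreement (one adjacent swap allowed at n ~ 6000) and clear separation
  # of the extremes
  expect_gte(cor(pl$mean, 1:8, method = "spearman"), 0.95)
  expect_lt(pl$mean[1], pl$mean[8])
})

test_that("overdispersion_check flags only overdispersed fits", {
  dat <- data.frame(g = c("a", "b"), k = c(30, 70), f = c(70, 30))
  sat <- fit_binomial_glm(dat, "k", "f", "g")
  od <- overdispersion_check(sat)
  expect_true(is.na(od$deviance_ratio))  # saturated: df 0
  # well-specified binomial data: ratio near 1 across replicates
  set.seed(10)
  ratios <- replicate(60, {
    n <- 40
    d <- data.frame(g = factor(rep(letters[1:4], each = 10)))
    tot <- rep(50, n)
    p <- 1 / (1 + exp(-(0.3 * as.integer(d$g) - 1)))
    d$k <- rbinom(n, tot, p)
    d$f <- tot - d$k
    overdispersion_check(fit_binomial_glm(d, "k", "f", "g"))$deviance_ratio
  })
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.2)
  # beta-binomial data blow the ratio past the flag
  set.seed(11)
  d <- data.frame(g = factor(rep(letters[1:4], each = 10)))
  tot <- rep(80, 40)
  p <- rbeta(40, 2, 2)  # huge extra-binomial variation
  d$k <- rbinom(40, tot, p)
  d$f <- tot - d$k
  expect_message(od2 <- overdispersion_check(
    fit_binomial_glm(d, "k", "f", "g")), "WARN")
  expect_true(od2$flagged)
  expect_gt(od2$deviance_ratio, 1.5)
})

test_that("correlate_c_p reproduces the closed-form Pearson r", {
  expect_equal(correlate_c_p(c(a = 1, b = 2, c = 3),
                             c(a = 2, b = 4, c = 6))$r, 1)
  expect_equal(correlate_c_p(c(a = 1, b = 2, c = 3),
                             c(a = 6, b = 4, c = 2))$r, -1)
  set.seed(2)
  x <- setNames(rnorm(8), paste0("G", 1:8))
  y <- setNames(rnorm(8), paste0("G", 1:8))
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate_c_p(x, y)
  expect_equal(res$r, r_closed, tolerance = 1e-12)
  # subsets and degenerate input
  res2 <- correlate_c_p(x, y, subset = paste0("G", 1:4), label = "inbred")
  expect_equal(res2$n, 4)
  expect_true(is.na(correlate_c_p(c(a = 1, b = 1, c = 1), y[1:3])$r))
})
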