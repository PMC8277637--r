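# Synthetic polycross generator: field layout, mating events with
# genotype-specific parameters, Mendelian offspring genotypes with call
# noise, and the ground-truth tables the estimators are validated against.

#' Polycross field design
#'
#' Builds the plant roster of a polycross nursery: `n_blocks` blocks, each
#' holding `plants_per_genotype` single plants of every genotype, optionally
#' replicated over years. The default (8 genotypes x 8 blocks x 8 plants)
#' yields 512 plants, the standard layout for synthetic-cultivar seed
#' production trials.
#'
#' @param genotypes character vector of genotype ids (default `G1..G8`).
#' @param n_blocks number of blocks (default 8).
#' @param plants_per_genotype single plants of each genotype per block
#'   (default 8).
#' @param years vector of year labels (default `1`).
#' @return A `polycross_design`: list with the parameters and a `roster`
#'   data.frame (`plant_id`, `genotype`, `block`, `year`).
#' @export
make_design <- function(genotypes = paste0("G", 1:8), n_blocks = 8,
                        plants_per_genotype = 8, years = 1) {
  stopifnot(n_blocks >= 1, plants_per_genotype >= 1, length(genotypes) >= 1)
  if (length(genotypes) != 8)
    warning("polycross design with ", length(genotypes),
            " genotypes (the reference layout uses 8)")
  roster <- expand.grid(plant = seq_len(plants_per_genotype),
                        genotype = genotypes, block = seq_len(n_blocks),
                        year = years, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  roster$plant_id <- sprintf("Y%s_B%d_%s_P%d", roster$year, roster$block,
                             roster$genotype, roster$plant)
  roster <- roster[c("plant_id", "genotype", "block", "year")]
  structure(list(genotypes = genotypes, n_blocks = n_blocks,
                 plants_per_genotype = plants_per_genotype, years = years,
                 roster = roster),
            class = "polycross_design")
}

#' @export
print.polycross_design <- function(x, ...) {
  cat("polycross_design:", length(x$genotypes), "genotypes x", x$n_blocks,
      "blocks x", x$plants_per_genotype, "plants;",
      nrow(x$roster), "plants total\n")
  invisible(x)
}

#' Mating parameters of a polycross
#'
#' `cross_flower_rate` is the per-genotype probability X_g that a seed is
#' sired by cross-flower pollen (from a flower of another plant); the
#' complement collapses autogamous and geitonogamous selfing, which no
#' marker method can separate. Given a cross-flower event, the donor
#' genotype is sampled with probability proportional to
#' `donor_weight[d] * compatibility[mother, d]` over the donor pool
#' (the mother's own genotype included iff `include_intra`), and the donor
#' plant uniformly among that genotype's plants other than the mother.
#' With equal weights and the default 8-genotype pool the expected
#' intra-genotype share of cross-flower events is 1/8, matching the
#' imputation convention used by the P estimator.
#'
#' @param genotypes character vector of genotype ids.
#' @param cross_flower_rate scalar or per-genotype vector in \[0,1\]
#'   (default 0.5, a realistic mid-range outcrossing level for faba bean).
#' @param donor_weight scalar or per-genotype nonnegative pollen weight.
#' @param compatibility square nonnegative matrix `K[mother, donor]`
#'   (default all 1).
#' @param include_intra include the mother's own genotype in the donor pool
#'   (default TRUE).
#' @param year_effects optional named numeric vector of additive shifts on
#'   `logit(X_g)` per year.
#' @return A `mating_params` object.
#' @export
mating_params <- function(genotypes = paste0("G", 1:8),
                          cross_flower_rate = 0.5, donor_weight = 1,
                          compatibility = NULL, include_intra = TRUE,
                          year_effects = NULL) {
  ng <- length(genotypes)
  x <- rep_len(cross_flower_rate, ng)
  w <- rep_len(donor_weight, ng)
  if (any(x < 0 | x > 1)) stop("cross_flower_rate must lie in [0,1]")
  if (any(w < 0)) stop("donor_weight must be nonnegative")
  if (is.null(compatibility)) compatibility <- matrix(1, ng, ng)
  compatibility <- as.matrix(compatibility)
  if (!all(dim(compatibility) == ng) || any(compatibility < 0))
    stop("compatibility must be a nonnegative ", ng, "x", ng, " matrix")
  dimnames(compatibility) <- list(genotypes, genotypes)
  structure(list(genotypes = genotypes,
                 cross_flower_rate = stats::setNames(x, genotypes),
                 donor_weight = stats::setNames(w, genotypes),
                 compatibility = compatibility,
                 include_intra = isTRUE(include_intra),
                 year_effects = year_effects),
            class = "mating_params")
}

#' Genotyping-call noise model
#'
#' Emulates KASP-style call failures: each offspring call is independently
#' dropped (set missing) with `missing_rate`, and otherwise corrupted with
#' `error_rate` by flipping one of its two bases to the marker's other
#' allele. These are the failure modes that trigger the paternity caller's
#' ignore-budget and the maternal-check resampling/omission rules.
#'
#' @param missing_rate per-call missing probability (default 0.02).
#' @param error_rate per-call substitution probability (default 0.01).
#' @return A `noise_model` object.
#' @export
noise_model <- function(missing_rate = 0.02, error_rate = 0.01) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  structure(list(missing_rate = missing_rate, error_rate = error_rate),
            class = "noise_model")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate mating events of a polycross
#'
#' Draws `seeds_per_plant` seeds for every plant in the roster. Each seed is
#' a Bernoulli(X_g) trial for cross-flower pollination; cross-flower seeds
#' receive a donor genotype and plant as described in [mating_params()], and
#' the event is labelled `self` (autogamous/geitonogamous), `intra`
#' (cross-flower, same genotype, different plant) or `inter` (different
#' genotype). The realized genetic degree of cross-fertilization of a
#' genotype is its share of `inter` events; its expectation is
#' `X_g * (1 - intra_share)`.
#'
#' @param design a `polycross_design`.
#' @param params a `mating_params` over the same genotypes.
#' @param seeds_per_plant sampled seeds per plant (default 12).
#' @param rng_seed integer seed; all draws are reproducible given it.
#' @return A `seed_truth` data.frame: `seed_id`, `mother_plant`,
#'   `mother_genotype`, `block`, `year`, `event`, `donor_genotype`,
#'   `donor_plant`.
#' @export
simulate_matings <- function(design, params, seeds_per_plant = 12,
                             rng_seed = 1L) {
  stopifnot(inherits(design, "polycross_design"),
            inherits(params, "mating_params"),
            setequal(design$genotypes, params$genotypes))
  set.seed(rng_seed)
  ros <- design$roster
  n_seed <- nrow(ros) * seeds_per_plant
  idx <- rep(seq_len(nrow(ros)), each = seeds_per_plant)
  mg <- ros$genotype[idx]
  yr <- ros$year[idx]
  x <- params$cross_flower_rate[mg]
  if (!is.null(params$year_effects)) {
    shift <- params$year_effects[as.character(yr)]
    shift[is.na(shift)] <- 0
    x <- inv_logit(logit(pmin(pmax(x, 1e-12), 1 - 1e-12)) + shift)
    x[params$cross_flower_rate[mg] == 0] <- 0
    x[params$cross_flower_rate[mg] == 1] <- 1
  }
  crossed <- stats::runif(n_seed) < x
  donor_g <- rep(NA_character_, n_seed)
  # donor genotype: one multinomial table per mother genotype
  for (g in design$genotypes) {
    rows <- which(crossed & mg == g)
    if (!length(rows)) next
    w <- params$donor_weight * params$compatibility[g, ]
    if (!params$include_intra) w[g] <- 0
    if (all(w == 0))
      stop("all donor weights zero for mother genotype ", g)
    donor_g[rows] <- sample(design$genotypes, length(rows), replace = TRUE,
                            prob = w)
  }
  donor_g[!crossed] <- mg[!crossed]
  # donor plant: uniform among the donor genotype's plants in the same year,
  # excluding the mother plant itself for cross-flower events
  donor_p <- ros$plant_id[idx]                       # self: same plant
  cross_rows <- which(crossed)
  if (length(cross_rows)) {
    key <- paste(yr, donor_g, sep = "\r")
    pools <- split(ros$plant_id, paste(ros$year, ros$genotype, sep = "\r"))
    donor_p[cross_rows] <- vapply(cross_rows, function(i) {
      pool <- pools[[key[i]]]
      pool <- pool[pool != ros$plant_id[idx[i]]]
      if (!length(pool))
        stop("no donor plant available for genotype ", donor_g[i])
      pool[sample.int(length(pool), 1L)]
    }, character(1))
  }
  event <- ifelse(!crossed, "self", ifelse(donor_g == mg, "intra", "inter"))
  out <- data.frame(
    seed_id = sprintf("S%06d", seq_len(n_seed)),
    mother_plant = ros$plant_id[idx], mother_genotype = mg,
    block = ros$block[idx], year = yr, event = event,
    donor_genotype = donor_g, donor_plant = donor_p,
    stringsAsFactors = FALSE)
  class(out) <- c("seed_truth", "data.frame")
  out
}

#' Mendelian offspring genotypes with call noise
#'
#' For every seed in the truth table, draws one allele from the mother's and
#' one from the father's call at each panel marker (unordered pair), then
#' applies the noise model: calls are dropped with `missing_rate` or have
#' one base substituted by the marker's other allele with `error_rate`.
#'
#' @param truth a `seed_truth` table from [simulate_matings()].
#' @param panel a `genotype_panel` containing every parent genotype.
#' @param noise a `noise_model` (default: noiseless).
#' @param rng_seed integer seed.
#' @param markers marker ids to genotype (default: all panel markers).
#' @return data.frame `seed_id`, `mother_plant`, `mother_genotype`, `block`,
#'   `year`, then one `"X/Y"`/`NA` call column per marker.
#' @export
genotype_offspring <- function(truth, panel, noise = noise_model(0, 0),
                               rng_seed = 1L, markers = NULL) {
  if (is.null(markers)) markers <- panel$markers$marker_id
  miss <- setdiff(unique(c(truth$mother_genotype, truth$donor_genotype)),
                  rownames(panel$calls))
  if (length(miss)) stop("parent genotype not in panel: ", miss[1])
  set.seed(rng_seed)
  n <- nrow(truth)
  out <- as.data.frame(truth)[c("seed_id", "mother_plant", "mother_genotype",
                                "block", "year")]
  class(out) <- "data.frame"
  for (m in markers) {
    mom <- call_bases(panel$calls[truth$mother_genotype, m])
    dad <- call_bases(panel$calls[truth$donor_genotype, m])
    if (anyNA(mom) || anyNA(dad))
      stop("a parent is missing a call at marker ", m)
    a1 <- ifelse(stats::runif(n) < 0.5, mom[, 1], mom[, 2])
    a2 <- ifelse(stats::runif(n) < 0.5, dad[, 1], dad[, 2])
    # noise: substitute one base by the marker's other allele
    if (noise$error_rate > 0) {
      mk <- panel$markers[panel$markers$marker_id == m, ]
      err <- stats::runif(n) < noise$error_rate
      which_base <- stats::runif(n) < 0.5
      flip <- function(b) ifelse(b == mk$allele1, mk$allele2, mk$allele1)
      a1[err & which_base] <- flip(a1[err & which_base])
      a2[err & !which_base] <- flip(a2[err & !which_base])
    }
    cl <- format_call(a1, a2)
    if (noise$missing_rate > 0)
      cl[stats::runif(n) < noise$missing_rate] <- NA_character_
    out[[m]] <- cl
  }
  out
}

#' Write simulator outputs as TSV files
#'
#' Writes `truth.tsv` and `calls.tsv` under `dir` (LF line endings, `NA`
#' for missing). [read_truth()] and [read_calls()] round-trip them.
#'
#' @param truth seed truth table.
#' @param calls offspring call table.
#' @param dir output directory (created if absent).
#' @return named character vector of the two paths, invisibly.
#' @export
write_sim_outputs <- function(truth, calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, "truth.tsv")
  cp <- file.path(dir, "calls.tsv")
  write_tsv(truth, tp)
  write_tsv(calls, cp)
  invisible(c(truth = tp, calls = cp))
}

#' @rdname write_sim_outputs
#' @param path file path.
#' @export
read_truth <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  class(out) <- c("seed_truth", "data.frame")
  out
}

#' @rdname write_sim_outputs
#' @export
read_calls <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}

write_tsv <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Reference 8-genotype SNP panel
#'
#' Builds the synthetic stand-in for a polycross candidate panel: eight
#' genotypes (six inbred lines and two F1 hybrids, plus the hybrids' four
#' parental lines as non-candidate records), a 3-marker identification set
#' and a 4-marker validation set at which all candidates are homozygous with
#' pairwise-distinct signatures (minimum pairwise Hamming distance 3 over
#' the 7 markers), and two confirmation markers at which only the F1s are
#' heterozygous. Signatures encode the genotype index in binary over the
#' marker alleles.
#'
#' @param genotypes ids of the eight candidates (default `G1..G8`).
#' @return a validated `genotype_panel` with 12 records.
#' @export
make_default_panel <- function(genotypes = paste0("G", 1:8)) {
  stopifnot(length(genotypes) == 8)
  bits <- t(vapply(0:7, function(i) as.integer(intToBits(i))[1:3], integer(3)))
  par_bit <- rowSums(bits) %% 2
  base_of <- function(b, a0, a1) ifelse(b == 0, a0, a1)
  sig <- cbind(base_of(bits[, 1], "A", "G"), base_of(bits[, 2], "A", "G"),
               base_of(bits[, 3], "A", "G"),
               base_of(bits[, 1], "C", "T"), base_of(bits[, 2], "C", "T"),
               base_of(bits[, 3], "C", "T"), base_of(par_bit, "A", "C"))
  mids <- paste0("m", 1:7)
  markers <- data.frame(
    marker_id = c(mids, "c1", "c2"),
    allele1 = c("A", "A", "A", "C", "C", "C", "A", "A", "A"),
    allele2 = c("G", "G", "G", "T", "T", "T", "C", "G", "G"),
    stringsAsFactors = FALSE)
  f1_parents <- c("L1", "L2", "L3", "L4")
  ids <- c(genotypes, f1_parents)
  calls <- matrix(NA_character_, length(ids), nrow(markers),
                  dimnames = list(ids, markers$marker_id))
  for (i in 1:8) calls[genotypes[i], mids] <- paste0(sig[i, ], "/", sig[i, ])
  # G7 = L1 x L2, G8 = L3 x L4; parents share the hybrid's id/validation
  # signature but differ at the confirmation markers
  calls["L1", mids] <- calls["L2", mids] <- calls[genotypes[7], mids]
  calls["L3", mids] <- calls["L4", mids] <- calls[genotypes[8], mids]
  calls[, "c1"] <- "A/A"; calls[, "c2"] <- "A/A"
  calls["L2", c("c1", "c2")] <- c("G/G", "G/G")
  calls["L4", c("c1", "c2")] <- c("G/G", "G/G")
  calls[genotypes[7], c("c1", "c2")] <- c("A/G", "A/G")
  calls[genotypes[8], c("c1", "c2")] <- c("A/G", "A/G")
  genos <- data.frame(
    genotype_id = ids,
    class = c(rep("inbred", 6), "F1", "F1", rep("inbred", 4)),
    parent1 = c(rep(NA, 6), "L1", "L3", rep(NA, 4)),
    parent2 = c(rep(NA, 6), "L2", "L4", rep(NA, 4)),
    stringsAsFactors = FALSE)
  genotype_panel(markers, genos, calls,
                 id_set = mids[1:3], validation_set = mids[4:7],
                 confirmation_set = c("c1", "c2"), candidates = genotypes)
}
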