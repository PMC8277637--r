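# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive results by brute force / first principles and
# never call the package code paths they are used to check.

# ---- IRLS oracle: weighted logistic fit of cbind(k, n - k) ~ X ------------
oracle_irls <- function(X, k, n, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  ok <- n > 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- n * mu * (1 - mu)
    z <- eta + (k / pmax(n, 1) - mu) / (mu * (1 - mu))
    Xo <- X[ok, , drop = FALSE]
    XW <- Xo * w[ok]
    beta_new <- drop(solve(crossprod(Xo, XW), crossprod(XW, z[ok])))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# ---- brute-force minimal distinguishing set -------------------------------
# sig: candidates x markers matrix of single bases; returns smallest subset
# (lexicographically first among equal-size optima, markers pre-sorted)
oracle_min_set <- function(sig) {
  m <- ncol(sig)
  for (k in seq_len(m)) {
    combos <- utils::combn(m, k)
    for (i in seq_len(ncol(combos))) {
      idx <- combos[, i]
      if (!anyDuplicated(apply(sig[, idx, drop = FALSE], 1, paste,
                               collapse = "")))
        return(colnames(sig)[idx])
    }
  }
  NULL
}

# random all-homozygous panel with distinct signatures, for property tests
random_hom_panel <- function(n_geno = 8, n_marker = 12, seed = 1) {
  set.seed(seed)
  repeat {
    sig <- matrix(sample(c("A", "G"), n_geno * n_marker, replace = TRUE),
                  n_geno, n_marker,
                  dimnames = list(paste0("R", seq_len(n_geno)),
                                  paste0("m", sprintf("%02d", seq_len(n_marker)))))
    if (!anyDuplicated(apply(sig, 1, paste, collapse = ""))) break
  }
  markers <- data.frame(marker_id = colnames(sig), allele1 = "A", allele2 = "G",
                        stringsAsFactors = FALSE)
  genos <- data.frame(genotype_id = rownames(sig), class = "inbred",
                      parent1 = NA_character_, parent2 = NA_character_,
                      stringsAsFactors = FALSE)
  calls <- matrix(paste0(sig, "/", sig), nrow(sig), ncol(sig),
                  dimnames = dimnames(sig))
  list(panel = genotype_panel(markers, genos, calls), sig = sig)
}

# ---- brute-force father matching (explicit ignore-subset enumeration) -----
oracle_match <- function(paternal, signatures, max_ignored = 2) {
  m <- length(paternal)
  missing_pos <- which(is.na(paternal))
  if (length(missing_pos) > max_ignored) return(list(status = "unassigned"))
  matches_on <- function(g, keep) {
    keep <- setdiff(keep, missing_pos)
    all(signatures[g, keep] == paternal[keep])
  }
  for (k in 0:max_ignored) {
    if (length(missing_pos) > k) next
    # all ignore sets of size k containing every missing position
    extra <- setdiff(seq_len(m), missing_pos)
    n_extra <- k - length(missing_pos)
    sets <- if (n_extra == 0) list(missing_pos)
      else apply(utils::combn(extra, n_extra), 2,
                 function(e) c(missing_pos, e), simplify = FALSE)
    if (k == 0 && length(missing_pos) == 0) sets <- list(integer())
    hit <- unique(unlist(lapply(sets, function(S) {
      keep <- setdiff(seq_len(m), S)
      which(vapply(seq_len(nrow(signatures)), matches_on, logical(1),
                   keep = keep))
    })))
    if (length(hit) == 1)
      return(list(status = "assigned", father = rownames(signatures)[hit],
                  n_ignored = k))
    if (length(hit) > 1)
      return(list(status = "ambiguous", n_ignored = k))
  }
  list(status = "unassigned")
}

# ---- brute-force compact-letter oracle: maximal cliques of the
# non-significance graph (feasible for <= 10 levels) ------------------------
oracle_cld_share <- function(sig) {
  k <- nrow(sig)
  nonsig <- !sig; diag(nonsig) <- TRUE
  subsets <- lapply(seq_len(2^k) - 1, function(x) which(intToBits(x)[1:k] == 1))
  is_clique <- vapply(subsets, function(s)
    length(s) > 0 && all(nonsig[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(cliques, function(s)
    !any(vapply(cliques, function(t)
      length(t) > length(s) && all(s %in% t), logical(1))), logical(1))]
  share <- matrix(FALSE, k, k)
  for (cl in maximal) share[cl, cl] <- TRUE
  diag(share) <- TRUE
  share
}

# ---- gene-dropping Monte Carlo for the founder-class engine ---------------
# N individuals, two labelled founder alleles each; selfing with prob s,
# otherwise father sampled proportional to per-individual pollen weight.
gene_drop <- function(n_founders = 8, N = 1e5, generations = 2, s = 0.5,
                      pollen_weight = function(a1, a2) rep(1, length(a1)),
                      seed = 1) {
  set.seed(seed)
  f <- sample.int(n_founders, N, replace = TRUE)
  a1 <- f; a2 <- f
  for (g in seq_len(generations)) {
    mom <- sample.int(N, N, replace = TRUE)
    w <- pollen_weight(a1, a2)
    dad <- sample.int(N, N, replace = TRUE, prob = w)
    selfed <- stats::runif(N) < s
    pick <- function(i) ifelse(stats::runif(length(i)) < 0.5, a1[i], a2[i])
    new1 <- pick(mom)
    new2 <- ifelse(selfed, pick(mom), pick(dad))
    a1 <- new1; a2 <- new2
  }
  mean(a1 == a2)
}

# ---- small end-to-end simulation used by several files --------------------
sim_batch <- function(rng_seed, x = 0.5, w = 1, noise = noise_model(0, 0),
                      seeds_per_plant = 12, n_blocks = 8) {
  panel <- make_default_panel()
  design <- make_design(panel$candidates, n_blocks = n_blocks)
  params <- mating_params(panel$candidates, cross_flower_rate = x,
                          donor_weight = w)
  truth <- simulate_matings(design, params, seeds_per_plant, rng_seed)
  calls <- genotype_offspring(truth, panel, noise, rng_seed + 1)
  calls$mother_genotype <- truth$mother_genotype
  list(panel = panel, truth = truth, calls = calls)
}
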