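# Estimation of the degree of cross-fertilization (C) and paternal
# outcrossing success (P): dataset construction with the 1/8 intra-genotype
# imputation, binomial-logit GLMs, sequential analysis of deviance,
# least-square means, Bonferroni contrasts with compact letter display,
# overdispersion diagnostics, and the C-P correlation.

#' Build the C dataset from assignments
#'
#' Joins all assigned seeds of the plants of one maternal genotype in one
#' block (and year) into a single unit of analysis: `n_cross` counts the
#' inter-genotype cross-fertilized seeds, `n_self` the remaining assigned
#' seeds (selfed or intra-genotype, indistinguishable by markers). The
#' default single-year polycross yields 8 x 8 = 64 rows.
#'
#' @param assignments assignment table (only `status == "assigned"` rows are
#'   used) with columns `mother_genotype`, `block`, `year`,
#'   `father_genotype`.
#' @param genotypes genotype ids fixing the factor levels (default: those
#'   present).
#' @param blocks,years level sets (default: those present).
#' @return data.frame `maternal_genotype`, `block`, `year`, `n_cross`,
#'   `n_self`; cells without seeds carry (0, 0).
#' @export
build_c_dataset <- function(assignments, genotypes = NULL, blocks = NULL,
                            years = NULL) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (is.null(genotypes)) genotypes <- sort(unique(assignments$mother_genotype))
  if (is.null(blocks)) blocks <- sort(unique(assignments$block))
  if (is.null(years)) years <- sort(unique(assignments$year))
  grid <- expand.grid(maternal_genotype = genotypes, block = blocks,
                      year = years, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  key <- function(g, b, y) paste(g, b, y, sep = "\r")
  inter <- a$father_genotype != a$mother_genotype
  kt <- key(a$mother_genotype, a$block, a$year)
  kg <- key(grid$maternal_genotype, grid$block, grid$year)
  grid$n_cross <- as.integer(tapply(inter, factor(kt, levels = kg), sum))
  grid$n_total <- as.integer(table(factor(kt, levels = kg)))
  grid$n_cross[is.na(grid$n_cross)] <- 0L
  grid$n_self <- grid$n_total - grid$n_cross
  grid$n_total <- NULL
  grid
}

#' Intra-genotype imputation for one maternal cell
#'
#' Markers cannot separate intra-genotype cross-fertilization from selfing,
#' so the diagonal (mother-sired) count of a maternal genotype's donor
#' profile is set to the mean of the seven (in general, the other) donors'
#' counts. This raises the cell's cross-fertilized total by 1/7 and fixes
#' the diagonal share at exactly 1/8 whatever the counts — the convention
#' that the paternal outcrossing success of a genotype on itself is 1/8.
#'
#' @param counts named numeric vector of inter-genotype seed counts for the
#'   other donors of one maternal genotype x block (x year) cell.
#' @return list: `diagonal` (imputed count, fractional in general), `total`
#'   (new cell total), `diagonal_share` (1/8 for 7 donors, or
#'   `1/(n_donors+1)` in general; `NaN` only if `counts` is empty).
#' @export
impute_intra_genotype <- function(counts) {
  d <- mean(counts)
  tot <- sum(counts) + d
  list(diagonal = d, total = tot,
       diagonal_share = if (tot > 0) d / tot else 1 / (length(counts) + 1))
}

#' Build the pair-count table with imputed diagonal
#'
#' Counts assigned inter-genotype seeds per (maternal genotype, paternal
#' genotype, block, year) and applies [impute_intra_genotype()] to every
#' diagonal entry within its maternal cell. Off-diagonal entries stay
#' integer; diagonals are fractional in general.
#'
#' @inheritParams build_c_dataset
#' @return data.frame `maternal_genotype`, `paternal_genotype`, `block`,
#'   `year`, `seeds_sired`.
#' @export
build_pair_counts <- function(assignments, genotypes = NULL, blocks = NULL,
                              years = NULL) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (is.null(genotypes)) genotypes <- sort(unique(assignments$mother_genotype))
  if (is.null(blocks)) blocks <- sort(unique(assignments$block))
  if (is.null(years)) years <- sort(unique(assignments$year))
  grid <- expand.grid(paternal_genotype = genotypes,
                      maternal_genotype = genotypes,
                      block = blocks, year = years, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[c("maternal_genotype", "paternal_genotype", "block", "year")]
  inter <- a[a$father_genotype != a$mother_genotype, , drop = FALSE]
  kt <- paste(inter$mother_genotype, inter$father_genotype, inter$block,
              inter$year, sep = "\r")
  kg <- paste(grid$maternal_genotype, grid$paternal_genotype, grid$block,
              grid$year, sep = "\r")
  grid$seeds_sired <- as.numeric(table(factor(kt, levels = kg)))
  diag_rows <- grid$maternal_genotype == grid$paternal_genotype
  cell <- paste(grid$maternal_genotype, grid$block, grid$year, sep = "\r")
  for (cl in unique(cell[diag_rows])) {
    in_cell <- cell == cl
    off <- in_cell & !diag_rows
    grid$seeds_sired[in_cell & diag_rows] <-
      impute_intra_genotype(grid$seeds_sired[off])$diagonal
  }
  grid
}

#' Build the P dataset (pair-level binomial rows)
#'
#' One row per (maternal genotype, paternal genotype, block, year):
#' successes `k` = imputed seeds sired by that father on that maternal
#' cell, failures = the cell's cross-fertilized total minus `k`. The default
#' single-year polycross yields 8 x 8 x 8 = 512 rows.
#'
#' @param pair_counts output of [build_pair_counts()].
#' @return the input with added columns `n_cross_pg` (successes) and
#'   `n_cross_other` (failures).
#' @export
build_p_dataset <- function(pair_counts) {
  cell <- paste(pair_counts$maternal_genotype, pair_counts$block,
                pair_counts$year, sep = "\r")
  tot <- stats::ave(pair_counts$seeds_sired, cell, FUN = sum)
  out <- pair_counts
  out$n_cross_pg <- out$seeds_sired
  out$n_cross_other <- tot - out$seeds_sired
  out
}

#' Fit a binomial-logit GLM with ordered terms
#'
#' Wraps `stats::glm(cbind(successes, failures) ~ ..., family = binomial)`
#' keeping the user's term entry order (which fixes the sequential analysis
#' of deviance). Fractional successes — produced by the 1/8 imputation —
#' are retained and fitted as weighted logistic responses
#' (quasi-likelihood); the harmless "non-integer #successes" warning is
#' suppressed. Non-convergence and complete separation (|logit| > 15 on
#' some fitted cell) are flagged, not raised.
#'
#' @param data dataset with the factor columns named in `terms`.
#' @param successes,failures column names of the two response counts.
#' @param terms character vector of model terms in entry order, e.g.
#'   `c("maternal_genotype", "block")` or
#'   `c("paternal_genotype", "maternal_genotype",
#'   "paternal_genotype:maternal_genotype", "block")`.
#' @return object of class `px_glm`: list with `fit` (the `glm`), `terms`,
#'   `converged`, `separation`.
#' @export
fit_binomial_glm <- function(data, successes, failures, terms) {
  for (v in all.vars(stats::reformulate(terms)))
    data[[v]] <- factor(data[[v]])
  fml <- stats::as.formula(paste0("cbind(", successes, ", ", failures, ") ~ ",
                                  paste(terms, collapse = " + ")))
  # keep.order preserves the user's sequential entry order (base R would
  # push interactions after all main effects, changing the deviance table)
  tt <- stats::terms(fml, keep.order = TRUE)
  fit <- withCallingHandlers(
    stats::glm(tt, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sep <- any(abs(fit$linear.predictors) > 15)
  structure(list(fit = fit, terms = terms, converged = fit$converged,
                 separation = sep, data = data,
                 successes = successes, failures = failures),
            class = "px_glm")
}

#' @export
print.px_glm <- function(x, ...) {
  cat("binomial-logit GLM:", deparse(stats::formula(x$fit)), "\n")
  cat("  deviance:", format(x$fit$deviance), "on", x$fit$df.residual, "df;",
      if (x$converged) "converged" else "NOT converged",
      if (x$separation) "(separation flagged)" else "", "\n")
  invisible(x)
}

#' Sequential analysis-of-deviance table
#'
#' Adds the model terms sequentially (in the order they were given to
#' [fit_binomial_glm()]) and reports, per term, the degrees of freedom, the
#' change in deviance, and the p value of the likelihood-ratio chi-squared
#' test. The null df is the number of dataset rows minus one; the term
#' deviances and the residual deviance add up exactly to the null deviance.
#' Aliased (rank-deficient) terms appear with their reduced df.
#'
#' @param fit a `px_glm`.
#' @return data.frame `term`, `df`, `deviance`, `p_value`, with `Null` and
#'   `Residual` rows.
#' @export
deviance_table <- function(fit) {
  an <- suppressWarnings(stats::anova(fit$fit, test = "Chisq"))
  n <- nrow(fit$data)
  null_dev <- fit$fit$null.deviance
  term_rows <- rownames(an)[-1]
  df <- an$Df[-1]
  dev <- an$Deviance[-1]
  p <- stats::pchisq(dev, df, lower.tail = FALSE)
  null_df <- n - 1L
  res_df <- null_df - sum(df)
  out <- data.frame(
    term = c("Null", term_rows, "Residual"),
    df = c(null_df, df, res_df),
    deviance = c(null_dev, dev, fit$fit$deviance),
    p_value = c(NA, p, NA),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Least-square means of a factor on the logit scale
#'
#' Marginal means over a complete grid of all model factors with equal
#' weights: for each level of `factor`, the linear predictors of every
#' combination of the other factors' levels are averaged, the standard
#' error is obtained from the coefficient covariance, the 95% confidence
#' interval uses the normal multiplier 1.96, and means and intervals are
#' back-transformed with the inverse logit. Levels fitted at an infinite
#' logit (separation) are reported with degenerate intervals and a warning.
#'
#' @param fit a `px_glm`.
#' @param factor name of a factor in the model.
#' @return data.frame `level`, `logit_mean`, `se`, `ci_lo`, `ci_hi`,
#'   `mean`, `mean_lo`, `mean_hi`, plus the averaging matrix as attribute
#'   `"L"` (used by [lsmean_contrasts()]).
#' @export
ls_means <- function(fit, factor) {
  g <- fit$fit
  tt <- stats::delete.response(stats::terms(g))
  vars <- all.vars(tt)
  if (!factor %in% vars) stop("'", factor, "' is not a factor in the model")
  xlev <- g$xlevels
  grid <- expand.grid(xlev[vars], stringsAsFactors = TRUE,
                      KEEP.OUT.ATTRS = FALSE)
  X <- stats::model.matrix(tt, grid, contrasts.arg = g$contrasts)
  beta <- stats::coef(g)
  if (anyNA(beta)) {
    X <- X[, !is.na(beta), drop = FALSE]
    beta <- beta[!is.na(beta)]
  }
  V <- stats::vcov(g)
  lev <- xlev[[factor]]
  L <- t(vapply(lev, function(l) colMeans(X[grid[[factor]] == l, , drop = FALSE]),
                numeric(ncol(X))))
  est <- drop(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  infinite <- abs(est) > 15
  if (any(infinite))
    warning("level(s) ", paste(lev[infinite], collapse = ", "),
            " at (near-)infinite logit: degenerate interval reported")
  lo <- est - 1.96 * se
  hi <- est + 1.96 * se
  out <- data.frame(level = lev, logit_mean = est, se = se,
                    ci_lo = lo, ci_hi = hi,
                    mean = inv_logit(est), mean_lo = inv_logit(lo),
                    mean_hi = inv_logit(hi),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "L") <- L
  attr(out, "vcov") <- V
  attr(out, "beta") <- beta
  attr(out, "factor") <- factor
  out
}

#' Contrasts of least-square means with Bonferroni correction
#'
#' Wald z-tests on the logit scale for a family of contrasts among the
#' levels of an LS-mean set: by default all pairwise differences,
#' optionally preceded by a group contrast (e.g. inbred lines vs F1
#' hybrids, as equal-weight averages of the group members). Adjusted p
#' values are `min(1, m * p)` with `m` the number of contrasts in the
#' declared family. A compact letter display is derived from the adjusted
#' pairwise decisions by insert-and-absorb, so two levels share a letter
#' iff their difference is not significant.
#'
#' @param lsm output of [ls_means()].
#' @param groups optional named list of level vectors; adds one contrast
#'   `mean(group1) - mean(group2)` per pair of groups to the family.
#' @param alpha significance level for the letter display (default 0.05).
#' @param pairwise_within optional level subset: pairwise contrasts are
#'   restricted to it (letters are computed for those levels).
#' @return list with `contrasts` (data.frame `contrast`, `estimate`, `se`,
#'   `z`, `p_value`, `p_adjusted`, `m`) and `letters` (named character
#'   vector).
#' @export
lsmean_contrasts <- function(lsm, groups = NULL, alpha = 0.05,
                             pairwise_within = NULL) {
  L <- attr(lsm, "L")
  V <- attr(lsm, "vcov")
  lev <- lsm$level
  if (is.null(pairwise_within)) pairwise_within <- lev
  rows <- list(); nms <- character()
  if (!is.null(groups) && length(groups) >= 2) {
    gp <- utils::combn(names(groups), 2)
    for (i in seq_len(ncol(gp))) {
      g1 <- groups[[gp[1, i]]]; g2 <- groups[[gp[2, i]]]
      cvec <- colMeans(L[match(g1, lev), , drop = FALSE]) -
        colMeans(L[match(g2, lev), , drop = FALSE])
      rows <- c(rows, list(cvec))
      nms <- c(nms, paste(gp[1, i], "-", gp[2, i]))
    }
  }
  pw <- utils::combn(pairwise_within, 2)
  pw_idx <- length(rows) + seq_len(ncol(pw))
  for (i in seq_len(ncol(pw))) {
    cvec <- L[match(pw[1, i], lev), ] - L[match(pw[2, i], lev), ]
    rows <- c(rows, list(cvec))
    nms <- c(nms, paste(pw[1, i], "-", pw[2, i]))
  }
  C <- do.call(rbind, rows)
  est <- drop(C %*% attr(lsm, "beta"))
  se <- sqrt(rowSums((C %*% V) * C))
  if (any(se == 0))
    stop("inestimable contrast: ", nms[se == 0][1])
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  m <- length(p)
  padj <- pmin(1, m * p)
  contrasts <- data.frame(contrast = nms, estimate = est, se = se, z = z,
                          p_value = p, p_adjusted = padj, m = m,
                          stringsAsFactors = FALSE, row.names = NULL)
  # significance matrix over the pairwise family
  k <- length(pairwise_within)
  sig <- matrix(FALSE, k, k, dimnames = list(pairwise_within, pairwise_within))
  for (i in seq_len(ncol(pw))) {
    s <- padj[pw_idx[i]] < alpha
    sig[pw[1, i], pw[2, i]] <- sig[pw[2, i], pw[1, i]] <- s
  }
  list(contrasts = contrasts, letters = compact_letters(sig))
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: start from one letter covering all levels;
#' for every significantly different pair occurring together in a letter
#' column, split the column in two (dropping one member each), then absorb
#' columns contained in others. The result guarantees that two levels share
#' a letter iff they are not significantly different.
#'
#' @param sig logical symmetric matrix, `TRUE` = significantly different,
#'   dimnames = levels.
#' @return named character vector of letter strings.
#' @export
compact_letters <- function(sig) {
  lev <- rownames(sig)
  k <- length(lev)
  cols <- list(rep(TRUE, k))                 # membership vectors
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols <- c(cols, list(b))
      }
    }
    # absorb: drop columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (x in seq_along(cols)) for (y in seq_along(cols)) {
      if (x != y && keep[x] && keep[y] &&
          all(cols[[x]] <= cols[[y]]) && any(cols[[x]] < cols[[y]]))
        keep[x] <- FALSE
      else if (x < y && keep[x] && keep[y] &&
               identical(cols[[x]], cols[[y]]))
        keep[y] <- FALSE
    }
    cols <- cols[keep]
  }
  # deterministic letter order: by first member index
  ord <- order(vapply(cols, function(c) which(c)[1], integer(1)))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(i)
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
  stats::setNames(out, lev)
}

#' Per-donor paternal outcrossing success from the P model
#'
#' LS means of the paternal-genotype factor of a fitted P model,
#' back-transformed to the proportion scale. By construction of the
#' response the eight donors' shares sum to one within every maternal cell
#' and the imputed self-share is exactly 1/8, so the average P is 12.5%
#' before GLM smoothing.
#'
#' @param fit a `px_glm` fitted on a P dataset.
#' @param factor paternal factor name (default `"paternal_genotype"`).
#' @return as [ls_means()].
#' @export
estimate_p <- function(fit, factor = "paternal_genotype") {
  ls_means(fit, factor)
}

#' Overdispersion diagnostics for a binomial GLM
#'
#' Residual deviance and Pearson chi-squared, each divided by the residual
#' degrees of freedom; a ratio above `flag_above` signals overdispersion.
#'
#' @param fit a `px_glm`.
#' @param flag_above flag threshold (default 1.5).
#' @return list `deviance_ratio`, `pearson_ratio`, `df`, `flagged`
#'   (ratios are `NA` when `df == 0`).
#' @export
overdispersion_check <- function(fit, flag_above = 1.5) {
  g <- fit$fit
  df <- g$df.residual
  if (df <= 0)
    return(list(deviance_ratio = NA_real_, pearson_ratio = NA_real_,
                df = df, flagged = FALSE))
  pearson <- sum(stats::residuals(g, type = "pearson")^2)
  dr <- g$deviance / df
  pr <- pearson / df
  flagged <- is.finite(dr) && dr > flag_above
  if (flagged)
    message("WARN: overdispersion flagged (deviance/df = ", format(dr), ")")
  list(deviance_ratio = dr, pearson_ratio = pr, df = df, flagged = flagged)
}

#' Pearson correlation of C and P estimates
#'
#' Product-moment correlation of paired genotype-level values (typically
#' back-transformed LS means of C and P), with the two-sided t-test p
#' value; computed for all genotypes or a subset (e.g. inbred lines only).
#'
#' @param c_values,p_values named numeric vectors (names = genotype ids).
#' @param subset optional genotype ids to restrict to.
#' @param label subset label carried in the result.
#' @return data.frame `subset`, `r`, `p_value`, `n`; `r` is `NA` when a
#'   vector has zero variance, `p_value` `NA` when `n < 3`.
#' @export
correlate_c_p <- function(c_values, p_values, subset = NULL, label = "all") {
  ids <- intersect(names(c_values), names(p_values))
  if (!is.null(subset)) ids <- intersect(ids, subset)
  x <- c_values[ids]; y <- p_values[ids]
  n <- length(ids)
  if (n < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(subset = label, r = NA_real_, p_value = NA_real_, n = n))
  if (n < 3) {
    return(data.frame(subset = label, r = stats::cor(x, y),
                      p_value = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(subset = label, r = unname(ct$estimate),
             p_value = ct$p.value, n = n, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
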