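# Paternity assignment for polycross offspring: maternal-allele attribution,
# mismatch-tolerant matching against candidate signatures, batch processing
# with the resample/omit rule, and seed classification.

#' Infer the paternal allele of an offspring call
#'
#' For a marker at which the maternal genotype is homozygous, the base
#' belonging to the mother is identified and the other base of the
#' offspring call is attributed to the father. A homozygous call equal to
#' the maternal base means the father transmitted the same base. A call
#' containing no maternal base is a maternal mismatch, returned as the value
#' `"mismatch"` (not an error): it triggers the resampling/omission rule at
#' batch level.
#'
#' @param offspring_call `"X/Y"` call string(s), or `NA` for missing.
#' @param maternal_base single base(s) carried by the (homozygous) mother.
#' @return character vector: the paternal base, `NA` for missing, or
#'   `"mismatch"`.
#' @export
infer_paternal_allele <- function(offspring_call, maternal_base) {
  b <- call_bases(offspring_call)
  n <- length(offspring_call)
  maternal_base <- rep_len(maternal_base, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(offspring_call)
  has1 <- b[, 1] == maternal_base
  has2 <- b[, 2] == maternal_base
  out[ok & has1] <- b[ok & has1, 2]      # other base (== maternal if hom call)
  out[ok & !has1 & has2] <- b[ok & !has1 & has2, 1]
  out[ok & !has1 & !has2] <- "mismatch"
  out
}

#' Match a paternal allele vector against candidate signatures
#'
#' Implements the iterative mismatch-tolerant father search. Level 0 accepts
#' a candidate whose signature matches the inferred paternal vector exactly,
#' with no missing position. If no candidate matches, single positions are
#' ignored iteratively (level 1), then pairs (level 2), up to `max_ignored`.
#' Missing positions consume the ignore budget first: a missing call is
#' informationally identical to an ignored one. At each level the union of
#' candidates matching under any admissible ignore set must be a single
#' genotype; a union of two or more yields status `ambiguous`, an empty
#' union escalates to the next level, and exhaustion of the budget yields
#' `unassigned` (as does a vector with more missing positions than the
#' budget allows).
#'
#' Equivalently: a candidate is in the level-k union iff its number of
#' signature mismatches plus the number of missing positions is `<= k`, so
#' the deciding level is the minimum of that score over candidates.
#'
#' @param paternal named character vector of paternal bases (`NA` missing),
#'   names = marker ids.
#' @param signatures candidates x markers character matrix of single bases
#'   (from [signature_matrix()] / [paternal_signature()]).
#' @param max_ignored ignore budget (default 2).
#' @return list with `status` (`assigned`/`ambiguous`/`unassigned`),
#'   `father` (id or `NA`), `n_ignored`, `ignored_markers`.
#' @export
match_father <- function(paternal, signatures, max_ignored = 2) {
  stopifnot(ncol(signatures) == length(paternal))
  missing_pos <- which(is.na(paternal))
  n_missing <- length(missing_pos)
  if (n_missing > max_ignored)
    return(list(status = "unassigned", father = NA_character_,
                n_ignored = NA_integer_, ignored_markers = character()))
  obs <- which(!is.na(paternal))
  sub <- signatures[, obs, drop = FALSE]
  ref <- matrix(paternal[obs], nrow(sub), length(obs), byrow = TRUE)
  nm <- as.integer(rowSums(sub != ref))
  score <- nm + n_missing
  k <- min(score)
  if (k > max_ignored)
    return(list(status = "unassigned", father = NA_character_,
                n_ignored = NA_integer_, ignored_markers = character()))
  hits <- which(score == k)
  if (length(hits) > 1)
    return(list(status = "ambiguous", father = NA_character_,
                n_ignored = as.integer(k), ignored_markers = character()))
  mism <- obs[signatures[hits, obs] != paternal[obs]]
  ign <- sort(c(missing_pos, mism))
  list(status = "assigned", father = rownames(signatures)[hits],
       n_ignored = as.integer(k),
       ignored_markers = colnames(signatures)[ign])
}

# vectorized core used by assign_batch: paternal is seeds x markers with NA
# for missing; returns data.frame(status, father, n_ignored)
match_father_batch <- function(paternal, signatures, max_ignored = 2) {
  nseed <- nrow(paternal)
  ncand <- nrow(signatures)
  n_missing <- rowSums(is.na(paternal))
  # mismatch counts seed x candidate
  nm <- matrix(0L, nseed, ncand)
  for (g in seq_len(ncand)) {
    cmp <- paternal != rep(signatures[g, ], each = nseed)
    nm[, g] <- rowSums(cmp, na.rm = TRUE)
  }
  score <- nm + n_missing
  best <- apply(score, 1, min)
  nbest <- rowSums(score == best)
  status <- ifelse(n_missing > max_ignored | best > max_ignored, "unassigned",
                   ifelse(nbest > 1, "ambiguous", "assigned"))
  father <- rep(NA_character_, nseed)
  ok <- status == "assigned"
  father[ok] <- rownames(signatures)[apply(score[ok, , drop = FALSE], 1,
                                           which.min)]
  n_ignored <- ifelse(status == "unassigned", NA_integer_, as.integer(best))
  n_ignored[status == "ambiguous"] <- as.integer(best[status == "ambiguous"])
  data.frame(status = status, father_genotype = father,
             n_ignored = n_ignored, stringsAsFactors = FALSE)
}

#' Assign fathers to a batch of offspring
#'
#' Runs the full per-seed protocol. First, every non-missing call on the
#' identification + validation markers is checked against the maternal
#' genotype; any maternal mismatch triggers a lookup in the optional
#' `resample_table` (a second call table keyed by `seed_id`, standing in
#' for re-genotyping) and the check is redone on the resampled calls; a
#' persistent mismatch (or absent resample entry) gives status
#' `maternal_mismatch` and the seed is omitted. Surviving seeds have their
#' paternal allele vector matched against the candidate signatures with
#' [match_father()] semantics.
#'
#' @param calls offspring call table (`seed_id`, `mother_plant` or
#'   `mother_genotype`, `block`, `year`, one column per marker).
#' @param panel a `genotype_panel`.
#' @param mothers optional named vector mapping `seed_id` (or mother plant)
#'   to maternal genotype; defaults to the `mother_genotype` column.
#' @param resample_table optional second call table with the same schema.
#' @param max_ignored ignore budget (default 2).
#' @param markers marker set used for matching (default: id + validation).
#' @return list with `assignments` (data.frame `seed_id`,
#'   `mother_genotype`, `block`, `year`, `status`, `father_genotype`,
#'   `n_ignored`) and `summary` (per-genotype sampled/assigned counts and
#'   identification rate; `NA` rate for zero seeds).
#' @export
assign_batch <- function(calls, panel, mothers = NULL, resample_table = NULL,
                         max_ignored = 2, markers = NULL) {
  if (is.null(markers)) markers <- c(panel$id_set, panel$validation_set)
  if (is.null(mothers)) {
    if (is.null(calls$mother_genotype))
      stop("calls lack a mother_genotype column and no `mothers` map given")
    mg <- calls$mother_genotype
  } else {
    mg <- unname(mothers[calls$seed_id])
  }
  unknown <- setdiff(unique(mg), rownames(panel$calls))
  if (length(unknown)) stop("mother genotype not in panel: ", unknown[1])
  cand <- panel$candidates
  sig <- signature_matrix(panel, cand, markers)
  nseed <- nrow(calls)
  res <- data.frame(
    seed_id = calls$seed_id, mother_genotype = mg,
    block = if (!is.null(calls$block)) calls$block else rep(NA, nseed),
    year = if (!is.null(calls$year)) calls$year else rep(NA, nseed),
    status = rep("unassigned", nseed),
    father_genotype = rep(NA_character_, nseed),
    n_ignored = rep(NA_integer_, nseed), stringsAsFactors = FALSE)
  if (nseed == 0) {
    return(list(assignments = res,
                summary = data.frame(mother_genotype = character(),
                                     sampled = integer(), assigned = integer(),
                                     identification_rate = numeric())))
  }
  mom_sig <- sig[mg, , drop = FALSE]     # mothers are candidates themselves
  paternal <- matrix(NA_character_, nseed, length(markers),
                     dimnames = list(NULL, markers))
  for (j in seq_along(markers))
    paternal[, j] <- infer_paternal_allele(calls[[markers[j]]], mom_sig[, j])
  mism <- rowSums(paternal == "mismatch", na.rm = TRUE) > 0
  if (any(mism)) {
    if (!is.null(resample_table)) {
      hit <- match(calls$seed_id[mism], resample_table$seed_id)
      redo <- which(mism)[!is.na(hit)]
      rrow <- hit[!is.na(hit)]
      for (j in seq_along(markers))
        paternal[redo, j] <- infer_paternal_allele(
          resample_table[[markers[j]]][rrow], mom_sig[redo, j])
      mism <- rowSums(paternal == "mismatch", na.rm = TRUE) > 0
    }
    res$status[mism] <- "maternal_mismatch"
  }
  keep <- which(!mism)
  if (length(keep)) {
    m <- match_father_batch(paternal[keep, , drop = FALSE], sig, max_ignored)
    res$status[keep] <- m$status
    res$father_genotype[keep] <- m$father_genotype
    res$n_ignored[keep] <- m$n_ignored
  }
  agg <- function(v) tapply(v, factor(mg, levels = sort(unique(mg))), sum)
  sampled <- agg(rep(1L, nseed))
  assigned <- agg(as.integer(res$status == "assigned"))
  summary <- data.frame(mother_genotype = names(sampled),
                        sampled = as.integer(sampled),
                        assigned = as.integer(assigned),
                        identification_rate = ifelse(sampled > 0,
                                                     assigned / sampled, NA),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(assignments = res, summary = summary)
}

#' Classify an assigned seed as selfed/intra or inter-genotype
#'
#' A father equal to the maternal genotype is genetically indistinguishable
#' from selfing (autogamy, geitonogamy, or intra-genotype cross) and is
#' classified `self_or_intra`; any other father is an inter-genotype
#' cross-fertilization.
#'
#' @param father_genotype,mother_genotype genotype ids (vectorized).
#' @param status assignment status; anything but `"assigned"` errors.
#' @return character vector `"self_or_intra"` / `"inter"`.
#' @export
classify_seed <- function(father_genotype, mother_genotype,
                          status = "assigned") {
  if (any(status != "assigned"))
    stop("classify_seed requires assigned seeds")
  ifelse(father_genotype == mother_genotype, "self_or_intra", "inter")
}

#' Confirm an F1 record is a true hybrid
#'
#' At each confirmation marker the two parents must be homozygous for
#' different alleles, so a true hybrid is heterozygous there; a selfed
#' (non-hybrid) plant is homozygous. A marker at which the parents carry
#' the same allele is uninformative and rejected.
#'
#' @param panel a `genotype_panel` containing the F1 and both parents.
#' @param f1_id genotype id of the putative hybrid (class `"F1"`).
#' @param markers confirmation marker ids (default: the panel's
#'   confirmation set).
#' @return `TRUE` iff the record is heterozygous at every marker.
#' @export
confirm_f1_hybrid <- function(panel, f1_id, markers = NULL) {
  if (is.null(markers)) markers <- panel$confirmation_set
  gt <- panel$genotypes
  rec <- gt[gt$genotype_id == f1_id, ]
  if (!nrow(rec)) stop("unknown genotype: ", f1_id)
  if (is.na(rec$parent1) || is.na(rec$parent2))
    stop("genotype ", f1_id, " has no recorded parents")
  for (m in markers) {
    p1 <- call_bases(panel$calls[rec$parent1, m])
    p2 <- call_bases(panel$calls[rec$parent2, m])
    if (anyNA(p1) || anyNA(p2) || p1[1] != p1[2] || p2[1] != p2[2])
      stop("confirmation marker ", m, " rejected: parents must be homozygous")
    if (p1[1] == p2[1])
      stop("confirmation marker ", m, " rejected: parents carry the same allele")
    f <- call_bases(panel$calls[f1_id, m])
    if (anyNA(f) || f[1] == f[2]) return(FALSE)
  }
  TRUE
}
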