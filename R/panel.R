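# SNP panels of candidate parents: construction, validation, file I/O, and
# selection of minimal / validation marker sets.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a genotype panel
#'
#' A `genotype_panel` holds biallelic SNP markers, candidate-parent genotype
#' records (inbred lines or F1 hybrids) with their calls, and three disjoint
#' marker sets: the minimal identification set (`id_set`), the validation set,
#' and the confirmation set used to verify that F1 hybrids are true hybrids.
#'
#' Calls are unordered base pairs written `"X/Y"` with `X <= Y` alphabetically,
#' or `NA` for missing. Genotypes used as pollen-donor candidates must be
#' homozygous at every marker of `id_set` and `validation_set` so that a
#' single-base paternal signature exists per genotype.
#'
#' @param markers data.frame with columns `marker_id`, `allele1`, `allele2`
#'   (two distinct bases from A/C/G/T).
#' @param genotypes data.frame with columns `genotype_id`, `class`
#'   (`"inbred"` or `"F1"`), `parent1`, `parent2` (genotype ids or `NA`;
#'   F1 records must carry both).
#' @param calls character matrix of `"X/Y"` call strings (or `NA`), rows
#'   named by `genotype_id`, columns by `marker_id`.
#' @param id_set,validation_set,confirmation_set character vectors of
#'   marker ids; pairwise disjoint.
#' @param candidates genotype ids eligible as pollen-donor candidates
#'   (default: all). Non-candidate records (e.g. the parental lines of F1
#'   hybrids, kept for hybrid confirmation) are exempt from the signature
#'   invariants.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(markers, genotypes, calls,
                           id_set = character(), validation_set = character(),
                           confirmation_set = character(), candidates = NULL) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "allele1", "allele2") %in% names(markers)),
            all(c("genotype_id", "class") %in% names(genotypes)))
  if (is.null(genotypes$parent1)) genotypes$parent1 <- NA_character_
  if (is.null(genotypes$parent2)) genotypes$parent2 <- NA_character_
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  rownames(calls) <- genotypes$genotype_id
  colnames(calls) <- markers$marker_id
  if (is.null(candidates)) candidates <- genotypes$genotype_id
  if (!all(candidates %in% genotypes$genotype_id))
    stop("candidate id not among genotypes: ",
         setdiff(candidates, genotypes$genotype_id)[1])
  panel <- structure(
    list(markers = markers, genotypes = genotypes, calls = calls,
         id_set = as.character(id_set),
         validation_set = as.character(validation_set),
         confirmation_set = as.character(confirmation_set),
         candidates = as.character(candidates)),
    class = "genotype_panel")
  validate_panel(panel)
  panel
}

#' Validate a genotype panel
#'
#' Checks marker allele domains, call strings, duplicate ids, F1 pedigree
#' completeness, homozygosity of all genotypes on `id_set` and
#' `validation_set`, disjointness of the marker sets, and that
#' `id_set` together with `validation_set` distinguishes all genotypes
#' pairwise (when both sets are non-empty).
#'
#' @param panel a `genotype_panel`.
#' @return `panel`, invisibly; errors describe the offending record.
#' @export
validate_panel <- function(panel) {
  mk <- panel$markers
  if (anyDuplicated(mk$marker_id))
    stop("duplicate marker_id: ", mk$marker_id[duplicated(mk$marker_id)][1])
  bad <- !(mk$allele1 %in% VALID_BASES) | !(mk$allele2 %in% VALID_BASES) |
    mk$allele1 == mk$allele2
  if (any(bad))
    stop("marker ", mk$marker_id[bad][1], ": needs two distinct bases from A/C/G/T")
  gt <- panel$genotypes
  if (anyDuplicated(gt$genotype_id))
    stop("duplicate genotype_id: ", gt$genotype_id[duplicated(gt$genotype_id)][1])
  if (!all(gt$class %in% c("inbred", "F1")))
    stop("genotype class must be 'inbred' or 'F1'")
  f1 <- gt$class == "F1"
  if (any(f1 & (is.na(gt$parent1) | is.na(gt$parent2))))
    stop("F1 record ", gt$genotype_id[f1 & (is.na(gt$parent1) | is.na(gt$parent2))][1],
         " lacks parent ids")
  # call strings: X/Y within the marker's allele pair
  for (j in seq_len(nrow(mk))) {
    cl <- panel$calls[, j]
    ok <- is.na(cl) | grepl("^[ACGT]/[ACGT]$", cl)
    if (!all(ok))
      stop("malformed call '", cl[!ok][1], "' at marker ", mk$marker_id[j])
    al <- c(mk$allele1[j], mk$allele2[j])
    bases <- call_bases(cl)
    ok <- is.na(cl) | (bases[, 1] %in% al & bases[, 2] %in% al)
    if (!all(ok))
      stop("call '", cl[!ok][1], "' at marker ", mk$marker_id[j],
           " uses a base outside its alleles {", al[1], ",", al[2], "}")
  }
  sets <- list(panel$id_set, panel$validation_set, panel$confirmation_set)
  allm <- unlist(sets)
  if (!all(allm %in% mk$marker_id))
    stop("marker set references unknown marker: ",
         setdiff(allm, mk$marker_id)[1])
  if (anyDuplicated(allm))
    stop("marker sets must be pairwise disjoint (", allm[duplicated(allm)][1], ")")
  idv <- c(panel$id_set, panel$validation_set)
  if (length(idv)) {
    sub <- panel$calls[panel$candidates, idv, drop = FALSE]
    b <- call_bases(sub)
    het <- !is.na(sub) & b[, 1] != b[, 2]
    if (any(het)) {
      w <- which(matrix(het, nrow = nrow(sub)), arr.ind = TRUE)[1, ]
      stop("genotype ", rownames(sub)[w[1]], " heterozygous at id/validation marker ",
           idv[w[2]])
    }
    if (length(panel$candidates) >= 2 && anyNA(sub)) {
      # missing calls on id/validation markers break signatures
      stop("missing call on an id/validation marker")
    }
    sig <- apply(sub, 1, paste, collapse = "")
    if (anyDuplicated(sig))
      stop("id_set + validation_set does not distinguish genotypes: ",
           paste(rownames(sub)[sig == sig[duplicated(sig)][1]], collapse = ", "))
  }
  invisible(panel)
}

# split "X/Y" strings into a two-column base matrix (NA rows for NA calls)
call_bases <- function(calls) {
  calls <- as.character(calls)
  out <- matrix(NA_character_, length(calls), 2)
  ok <- !is.na(calls)
  if (any(ok)) {
    sp <- matrix(unlist(strsplit(calls[ok], "/", fixed = TRUE)),
                 ncol = 2, byrow = TRUE)
    out[ok, ] <- sp
  }
  out
}

# canonical unordered call string, alphabetical order
format_call <- function(b1, b2) {
  ifelse(is.na(b1) | is.na(b2), NA_character_,
         paste(pmin(b1, b2), pmax(b1, b2), sep = "/"))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$genotypes), "genotypes x",
      nrow(x$markers), "markers\n")
  cat("  id_set:          ", paste(x$id_set, collapse = ", "), "\n")
  cat("  validation_set:  ", paste(x$validation_set, collapse = ", "), "\n")
  cat("  confirmation_set:", paste(x$confirmation_set, collapse = ", "), "\n")
  invisible(x)
}

#' Read a genotype panel from a TSV file
#'
#' Format: a comment header line `#alleles marker=X/Y ...` and optional
#' `#id_set`, `#validation_set`, `#confirmation_set` lines, then a
#' tab-separated table with columns
#' `genotype_id  class  parent1  parent2  <marker_id>...`; calls as `X/Y`
#' (X <= Y alphabetically) or `NA`.
#'
#' @param path file path.
#' @return a validated `genotype_panel`; `save_panel()` round-trips it
#'   byte-identically.
#' @seealso [save_panel()]
#' @export
load_panel <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get_set <- function(key) {
    ln <- grep(paste0("^#", key, "\\b"), meta, value = TRUE)
    if (!length(ln)) return(character())
    x <- strsplit(sub(paste0("^#", key, "\\s*"), "", ln[1]), "\\s+")[[1]]
    x[nzchar(x)]
  }
  al_ln <- get_set("alleles")
  if (!length(al_ln)) stop("panel file lacks '#alleles' header line")
  al_sp <- strsplit(al_ln, "=", fixed = TRUE)
  markers <- data.frame(
    marker_id = vapply(al_sp, `[`, "", 1),
    allele1 = vapply(al_sp, function(z) substr(z[2], 1, 1), ""),
    allele2 = vapply(al_sp, function(z) substr(z[2], 3, 3), ""),
    stringsAsFactors = FALSE)
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = "NA")
  need <- c("genotype_id", "class", "parent1", "parent2")
  if (!all(need %in% names(tab)))
    stop("panel table must start with columns: ", paste(need, collapse = ", "))
  mcols <- setdiff(names(tab), need)
  if (!setequal(mcols, markers$marker_id))
    stop("panel table marker columns do not match '#alleles' header")
  genotypes <- tab[need]
  genotypes$parent1 <- as.character(genotypes$parent1)
  genotypes$parent2 <- as.character(genotypes$parent2)
  calls <- as.matrix(tab[markers$marker_id])
  cand <- get_set("candidates")
  genotype_panel(markers, genotypes, calls,
                 id_set = get_set("id_set"),
                 validation_set = get_set("validation_set"),
                 confirmation_set = get_set("confirmation_set"),
                 candidates = if (length(cand)) cand else NULL)
}

#' Write a genotype panel to a TSV file
#'
#' @param panel a `genotype_panel`.
#' @param path file path.
#' @return `path`, invisibly.
#' @seealso [load_panel()]
#' @export
save_panel <- function(panel, path) {
  mk <- panel$markers
  hdr <- c(
    paste("#alleles", paste0(mk$marker_id, "=", mk$allele1, "/", mk$allele2,
                             collapse = " ")),
    if (length(panel$id_set))
      paste("#id_set", paste(panel$id_set, collapse = " ")),
    if (length(panel$validation_set))
      paste("#validation_set", paste(panel$validation_set, collapse = " ")),
    if (length(panel$confirmation_set))
      paste("#confirmation_set", paste(panel$confirmation_set, collapse = " ")),
    if (!setequal(panel$candidates, panel$genotypes$genotype_id))
      paste("#candidates", paste(panel$candidates, collapse = " ")))
  tab <- cbind(panel$genotypes[c("genotype_id", "class", "parent1", "parent2")],
               as.data.frame(panel$calls, stringsAsFactors = FALSE))
  con <- file(path, "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(tab, function(z) {
    z <- as.character(z); z[is.na(z)] <- "NA"; z
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Single-base paternal signature of a homozygous genotype
#'
#' For a genotype homozygous over `subset`, returns the one base it carries
#' at each marker, in `subset` order. This is the vector against which
#' inferred paternal alleles are matched.
#'
#' @param panel a `genotype_panel`.
#' @param genotype_id a genotype id present in the panel.
#' @param subset character vector of marker ids (may be empty).
#' @return named character vector of single bases.
#' @export
paternal_signature <- function(panel, genotype_id, subset) {
  if (!genotype_id %in% rownames(panel$calls))
    stop("unknown genotype: ", genotype_id)
  if (!length(subset)) return(stats::setNames(character(), character()))
  cl <- panel$calls[genotype_id, subset]
  b <- call_bases(cl)
  if (anyNA(cl))
    stop("genotype ", genotype_id, " missing call at ", subset[is.na(cl)][1])
  het <- b[, 1] != b[, 2]
  if (any(het))
    stop("genotype ", genotype_id, " heterozygous at ", subset[het][1],
         ": no single-base signature")
  stats::setNames(b[, 1], subset)
}

# markers at which every candidate is homozygous with no missing call
eligible_markers <- function(panel, candidates) {
  cl <- panel$calls[candidates, , drop = FALSE]
  ok <- vapply(seq_len(ncol(cl)), function(j) {
    b <- call_bases(cl[, j])
    !anyNA(cl[, j]) && all(b[, 1] == b[, 2])
  }, logical(1))
  colnames(cl)[ok]
}

# candidates x markers matrix of single signature bases
signature_matrix <- function(panel, candidates, markers) {
  t(vapply(candidates, function(g) paternal_signature(panel, g, markers),
           character(length(markers))))
}

all_distinct <- function(sig) {
  !anyDuplicated(apply(sig, 1, paste, collapse = ""))
}

#' Minimal marker set distinguishing all candidates
#'
#' Finds the smallest subset of eligible markers (markers at which every
#' candidate is homozygous and called) on which the candidates' single-base
#' signatures are pairwise distinct. The search enumerates subsets by
#' increasing size, iterating markers in lexicographic id order, so ties
#' between equal-size optima are broken deterministically (lexicographically
#' smallest sorted id list wins). At the scale this package targets
#' (<= 8 candidates, <= 20 markers) exhaustive enumeration is exact and cheap.
#'
#' @param panel a `genotype_panel`.
#' @param candidates genotype ids (default: all panel genotypes).
#' @param exclude marker ids to leave out of the search.
#' @return character vector of marker ids, sorted.
#' @export
minimal_distinguishing_set <- function(panel, candidates = NULL,
                                       exclude = character()) {
  if (is.null(candidates)) candidates <- panel$candidates
  if (length(candidates) < 2)
    stop("need at least two candidates to distinguish")
  elig <- sort(setdiff(eligible_markers(panel, candidates), exclude))
  if (!length(elig)) stop("no eligible (all-homozygous) markers")
  sig <- signature_matrix(panel, candidates, elig)
  full <- apply(sig, 1, paste, collapse = "")
  if (anyDuplicated(full)) {
    pair <- candidates[full == full[duplicated(full)][1]]
    stop("infeasible: candidates ", paste(pair, collapse = " and "),
         " identical over all eligible markers")
  }
  for (k in seq_along(elig)) {
    combos <- utils::combn(seq_along(elig), k)
    for (i in seq_len(ncol(combos))) {
      idx <- combos[, i]
      if (all_distinct(sig[, idx, drop = FALSE])) return(elig[idx])
    }
  }
  stop("unreachable")  # full set was checked distinct above
}

#' Select a disjoint validation marker set
#'
#' Picks `k` eligible markers outside `primary` that on their own distinguish
#' all candidates pairwise, mirroring the practice of confirming a paternity
#' call with an independent second marker set. Deterministic: the
#' lexicographically smallest qualifying k-subset is returned.
#'
#' @param panel a `genotype_panel`.
#' @param primary marker ids already used for identification.
#' @param k number of validation markers (default 4); `k = 0` returns an
#'   empty set.
#' @param candidates genotype ids (default: all).
#' @return character vector of `k` marker ids.
#' @export
select_validation_set <- function(panel, primary, k = 4, candidates = NULL) {
  if (k == 0) return(character())
  if (is.null(candidates)) candidates <- panel$candidates
  elig <- sort(setdiff(eligible_markers(panel, candidates), primary))
  if (length(elig) < k)
    stop("infeasible: only ", length(elig), " eligible markers outside primary")
  sig <- signature_matrix(panel, candidates, elig)
  combos <- utils::combn(seq_along(elig), k)
  for (i in seq_len(ncol(combos))) {
    idx <- combos[, i]
    if (all_distinct(sig[, idx, drop = FALSE])) return(elig[idx])
  }
  stop("infeasible: no disjoint distinguishing set of size ", k)
}
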