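# Exact inbreeding dynamics of synthetic cultivars. A population is a set
# of founder classes; each class carries a frequency and the joint
# distribution J of the founder origins of its two alleles (J[f, g] =
# probability the ordered allele pair descends from founders f and g).
# Founders are fully inbred and mutually unrelated, so identity by descent
# is identity of founder origin, and all of F, coancestry and the mating
# recursions reduce to exact linear algebra on J.

#' Founder class of a synthetic population
#'
#' @param freq class frequency in the population.
#' @param J square matrix of joint founder-origin probabilities for the
#'   ordered allele pair; entries nonnegative and summing to 1.
#' @return a `founder_class`; its inbreeding coefficient is `sum(diag(J))`
#'   and its allele (gamete) marginal is `(rowSums(J) + colSums(J)) / 2`.
#' @export
founder_class <- function(freq, J) {
  J <- as.matrix(J)
  stopifnot(freq >= 0, nrow(J) == ncol(J), all(J >= -1e-12),
            abs(sum(J) - 1) < 1e-9)
  structure(list(freq = freq, J = J), class = "founder_class")
}

class_F <- function(cl) sum(diag(cl$J))
class_marginal <- function(cl) (rowSums(cl$J) + colSums(cl$J)) / 2

#' Synthetic population of founder classes
#'
#' @param classes list of [founder_class()] objects over the same founder
#'   set; frequencies must sum to 1.
#' @param n_founders number of founders.
#' @param generation Syn generation index (0 = mixture of components).
#' @return a `syn_population`.
#' @export
syn_population <- function(classes, n_founders, generation = 0) {
  stopifnot(length(classes) >= 1,
            abs(sum(vapply(classes, `[[`, numeric(1), "freq")) - 1) < 1e-9,
            all(vapply(classes, function(c) nrow(c$J), integer(1)) ==
                  n_founders))
  structure(list(classes = classes, n_founders = n_founders,
                 generation = generation),
            class = "syn_population")
}

#' @export
print.syn_population <- function(x, ...) {
  cat("syn_population: Syn-", x$generation, ", ", length(x$classes),
      " classes over ", x$n_founders, " founders; mean F = ",
      format(mean_inbreeding(x)), "\n", sep = "")
  invisible(x)
}

#' Mating model of a synthetic generation
#'
#' `1 - C` of each class's offspring arise from (genetic) self-fertilization
#' in the broad sense used by the recursion (autogamy + geitonogamy); the
#' remainder receive cross pollen from a donor class sampled with
#' probability proportional to `frequency x pollen weight`. Pollen weights
#' are either given explicitly per class, or derived from a zero-P locus:
#' founders in `null_founders` carry a null paternal-success allele and a
#' class's weight is its probability of being functional under the chosen
#' inheritance mode (`"recessive"`: null only when homozygous null;
#' `"dominant"`: null whenever a null allele is present).
#'
#' @param C degree of cross-fertilization per class (scalar recycled, in
#'   \[0,1\]).
#' @param donor_weights optional explicit per-class nonnegative weights.
#' @param null_founders optional integer vector of founders carrying the
#'   null paternal-success allele.
#' @param null_p_mode `"recessive"` or `"dominant"` expression of the null.
#' @param external_pollen if `TRUE`, cross pollen comes from an unlimited
#'   unrelated external source (coancestry 0 with everything); used for the
#'   idealized single-population recursion.
#' @return a `syn_mating_model`.
#' @export
syn_mating_model <- function(C = 0.5, donor_weights = NULL,
                             null_founders = NULL,
                             null_p_mode = c("recessive", "dominant"),
                             external_pollen = FALSE) {
  null_p_mode <- match.arg(null_p_mode)
  stopifnot(all(C >= 0), all(C <= 1))
  structure(list(C = C, donor_weights = donor_weights,
                 null_founders = null_founders, null_p_mode = null_p_mode,
                 external_pollen = external_pollen),
            class = "syn_mating_model")
}

# pollen weight of each class under the model
class_pollen_weights <- function(population, model) {
  cls <- population$classes
  if (!is.null(model$donor_weights)) {
    w <- rep_len(model$donor_weights, length(cls))
  } else if (!is.null(model$null_founders)) {
    nf <- model$null_founders
    w <- vapply(cls, function(c) {
      p_null_hom <- sum(c$J[nf, nf, drop = FALSE])
      p_any_null <- sum(c$J[nf, , drop = FALSE]) +
        sum(c$J[, nf, drop = FALSE]) - p_null_hom
      if (model$null_p_mode == "recessive") 1 - p_null_hom else 1 - p_any_null
    }, numeric(1))
  } else {
    w <- rep(1, length(cls))
  }
  if (any(w < 0)) stop("negative pollen weight")
  w
}

#' Idealized inbreeding trajectory for constant C
#'
#' The unrelated-mate idealization (infinitely many components, no
#' coancestry between mates): starting from fully inbred founders,
#' `F_0 = 1` and `F_(t+1) = (1 - C) (1 + F_t) / 2`, whose fixed point is
#' the equilibrium `F_inf = (1 - C) / (1 + C)`. In particular
#' `F_1 = 1 - C`.
#'
#' @param C scalar degree of cross-fertilization in \[0,1\].
#' @param generations number of steps beyond Syn-0.
#' @return list with `F` (numeric vector `F_0 .. F_n`) and `F_inf`.
#' @export
idealized_f_trajectory <- function(C, generations) {
  stopifnot(C >= 0, C <= 1, generations >= 0)
  f <- numeric(generations + 1)
  f[1] <- 1
  for (t in seq_len(generations))
    f[t + 1] <- (1 - C) * (1 + f[t]) / 2
  list(F = f, F_inf = (1 - C) / (1 + C))
}

#' Reference scenarios of synthetic-cultivar propagation
#'
#' Both scenarios start from eight fully inbred, mutually unrelated
#' components at equal frequency (Syn-0) with a constant degree of
#' cross-fertilization of 0.5. Scenario `"one"` gives every line the same
#' pollen weight, with the mother's own genotype in the donor pool, so 1/8
#' of the cross events are intra-genotypic (genetically selfing).
#' Scenario `"two"` is the opposite extreme: seven lines have zero paternal
#' outcrossing success and fully realize their cross-fertilization with the
#' single siring line; that line finds no cross pollen and effectively
#' self-fertilizes, which lowers the population's mean genetic C by 1/8 —
#' the same value as in scenario one. The zero-P trait is carried by the
#' seven null founders and expressed in later generations according to
#' `null_p_mode`.
#'
#' @param name `"one"` or `"two"`.
#' @param n_founders number of components (default 8).
#' @param C degree of cross-fertilization (default 0.5).
#' @param null_p_mode inheritance of zero paternal success in scenario two.
#' @return list with `population` (Syn-0) and `model`.
#' @export
make_scenario <- function(name = c("one", "two"), n_founders = 8, C = 0.5,
                          null_p_mode = c("recessive", "dominant")) {
  name <- match.arg(name)
  null_p_mode <- match.arg(null_p_mode)
  classes <- lapply(seq_len(n_founders), function(i) {
    J <- matrix(0, n_founders, n_founders)
    J[i, i] <- 1
    founder_class(1 / n_founders, J)
  })
  pop <- syn_population(classes, n_founders, generation = 0)
  model <- switch(name,
    one = syn_mating_model(C = C),
    two = syn_mating_model(C = C, null_founders = seq_len(n_founders - 1),
                           null_p_mode = null_p_mode))
  list(population = pop, model = model)
}

#' Coancestry between founder classes
#'
#' With fully inbred, unrelated founders, two alleles are identical by
#' descent iff they descend from the same founder. For distinct
#' individuals, the coancestry is the dot product of the two classes'
#' allele marginals; for one individual with itself it is `(1 + F) / 2`.
#'
#' @param classA,classB `founder_class` objects over the same founders.
#' @param same_individual if `TRUE`, return the self-coancestry of
#'   `classA`.
#' @return scalar coancestry.
#' @export
coancestry <- function(classA, classB = classA, same_individual = FALSE) {
  if (same_individual) return((1 + class_F(classA)) / 2)
  sum(class_marginal(classA) * class_marginal(classB))
}

# selfing transition on a J matrix: offspring picks two alleles (with
# replacement) from the parent's pair
self_J <- function(J) {
  r <- rowSums(J); cs <- colSums(J)
  (diag(r + cs, nrow = nrow(J)) + J + t(J)) / 4
}

#' Advance a synthetic population by one generation
#'
#' Every class contributes a selfed offspring class (frequency
#' `freq x (1 - C)`, J from within-individual allele resampling) and a
#' crossed offspring class (frequency `freq x C`, J = outer product of the
#' mother's allele marginal and the pooled pollen marginal). The pollen
#' pool mixes all classes proportionally to `frequency x pollen weight`;
#' because J is linear in the donor distribution, pooling donors is exact.
#' Classes with (numerically) identical J are merged. With
#' `external_pollen`, cross pollen instead carries a fresh founder label
#' that is never identical by descent with existing alleles (the matrices
#' gain one row/column per generation).
#'
#' @param population a `syn_population`.
#' @param model a `syn_mating_model`.
#' @param merge_tol tolerance for J-matrix equality when merging classes.
#' @return the next `syn_population`.
#' @export
advance_generation <- function(population, model, merge_tol = 1e-12) {
  cls <- population$classes
  C <- rep_len(model$C, length(cls))
  nf <- population$n_founders
  if (model$external_pollen) {
    nf <- nf + 1
    cls <- lapply(cls, function(c) {
      J <- matrix(0, nf, nf)
      J[seq_len(nf - 1), seq_len(nf - 1)] <- c$J
      founder_class(c$freq, J)
    })
    pool <- c(rep(0, nf - 1), 1)
  } else {
    w <- class_pollen_weights(population, model)
    freq <- vapply(cls, `[[`, numeric(1), "freq")
    pw <- freq * w
    if (sum(pw) == 0) {
      if (any(C > 0))
        stop("all pollen weights are zero but some class has C > 0")
      pw <- freq  # irrelevant: no cross events
    }
    pw <- pw / sum(pw)
    marg <- vapply(cls, class_marginal, numeric(nf))
    pool <- drop(marg %*% pw)
  }
  out <- list()
  for (i in seq_along(cls)) {
    c <- cls[[i]]
    s <- 1 - C[i]
    if (s > 0)
      out <- c(out, list(founder_class(c$freq * s, self_J(c$J))))
    if (C[i] > 0)
      out <- c(out, list(founder_class(c$freq * C[i],
                                       outer(class_marginal(c), pool))))
  }
  out <- merge_classes(out, merge_tol)
  syn_population(out, nf, generation = population$generation + 1)
}

merge_classes <- function(classes, tol = 1e-12) {
  kept <- list()
  for (c in classes) {
    hit <- 0L
    for (k in seq_along(kept)) {
      if (max(abs(kept[[k]]$J - c$J)) <= tol) { hit <- k; break }
    }
    if (hit > 0L) kept[[hit]]$freq <- kept[[hit]]$freq + c$freq
    else kept <- c(kept, list(c))
  }
  kept
}

#' Mean inbreeding coefficient of a population
#'
#' @param population a `syn_population`.
#' @return frequency-weighted mean of the class inbreeding coefficients.
#' @export
mean_inbreeding <- function(population) {
  sum(vapply(population$classes, function(c) c$freq * class_F(c), numeric(1)))
}

#' Mean genetic degree of cross-fertilization under a model
#'
#' The genetic (marker-visible) C of a mother class is its cross-pollen
#' fraction times the probability that the sampled donor is not genetically
#' identical to the mother (a donor class with the same J as a fully inbred
#' mother yields offspring indistinguishable from selfed ones). Averaged
#' over classes by frequency.
#'
#' @param population a `syn_population`.
#' @param model a `syn_mating_model`.
#' @return scalar mean genetic C.
#' @export
mean_genetic_c <- function(population, model) {
  cls <- population$classes
  C <- rep_len(model$C, length(cls))
  if (model$external_pollen) return(sum(vapply(seq_along(cls), function(i)
    cls[[i]]$freq * C[i], numeric(1))))
  w <- class_pollen_weights(population, model)
  freq <- vapply(cls, `[[`, numeric(1), "freq")
  pw <- freq * w
  tot <- sum(pw)
  vals <- vapply(seq_along(cls), function(i) {
    if (C[i] == 0 || tot == 0) return(0)
    same <- vapply(seq_along(cls), function(j)
      if (max(abs(cls[[j]]$J - cls[[i]]$J)) <= 1e-12) pw[j] else 0,
      numeric(1))
    cls[[i]]$freq * C[i] * (1 - sum(same) / tot)
  }, numeric(1))
  sum(vals)
}

#' Mean-inbreeding trajectory of a scenario
#'
#' Runs [advance_generation()] repeatedly and records the mean inbreeding
#' coefficient and the number of distinct founder classes per generation.
#'
#' @param population starting `syn_population` (Syn-0).
#' @param model a `syn_mating_model`.
#' @param generations number of generations to advance.
#' @return data.frame `generation`, `mean_F`, `n_classes`.
#' @export
syn_trajectory <- function(population, model, generations) {
  out <- data.frame(generation = 0, mean_F = mean_inbreeding(population),
                    n_classes = length(population$classes))
  for (t in seq_len(generations)) {
    population <- advance_generation(population, model)
    out <- rbind(out, data.frame(generation = t,
                                 mean_F = mean_inbreeding(population),
                                 n_classes = length(population$classes)))
  }
  out
}
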