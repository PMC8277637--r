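---
title: "Mating-system estimation and inbreeding dynamics in polycross nurseries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mating-system estimation and inbreeding dynamics in polycross nurseries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycrossr)
```

## The problem

Partially allogamous crops such as faba bean reproduce by a mixture of
self-fertilization (autogamy and geitonogamy) and insect-mediated
cross-fertilization. Synthetic cultivars of such crops are built by mixing a
small number of selected components (generation Syn-0) and letting open
pollination propagate the stand (Syn-1, Syn-2, ...). Two genotype-specific
reproductive traits shape what that propagation does to the population:

* the **degree of cross-fertilization** $C_g$ — the share of genotype $g$'s
  seeds sired by a *different* genotype, and
* the **paternal outcrossing success** $P_g$ — genotype $g$'s share of the
  cross-fertilized seeds across all maternal plants of the stand.

Both are estimated from SNP genotypes of sampled seedlings in a polycross: a
replicated mixed stand where every genotype is mother and pollen donor at
once. This vignette documents the models, the synthetic-data generator that
stands in for undeposited field data, the numerical choices, and what the
test suite does and does not establish.

## Paternity assignment

Candidate parents are chosen to be homozygous at all identification and
validation SNPs (for F1 hybrids this means selecting SNPs at which both of
their parents carry the same allele), so each candidate reduces to a
single-base *signature* per marker. For each seedling call, the base
belonging to the homozygous mother is identified and the other base is
attributed to the father (`infer_paternal_allele`). A call containing no
maternal base is a *maternal mismatch*; the seedling is looked up in an
optional resample table and, if the mismatch persists, omitted — the desk
equivalent of re-genotyping a mislabelled sample.

Father matching (`match_father`) proceeds by ignore levels 0, 1, 2:

* level 0 — the paternal vector matches one signature exactly, with no
  missing call;
* level $k$ — over all ways of ignoring $k$ positions, where **missing
  positions consume the budget first** (a missing call is informationally an
  ignored one), collect every candidate compatible with the remainder. If
  the union over all admissible ignore sets is a single genotype, it is
  accepted with `n_ignored = k`; a union of two or more is `ambiguous`; an
  empty union escalates to the next level, and exhausting the budget leaves
  the seed `unassigned`.

The union rule is the conservative reading of "matched a unique genotype":
a candidate reachable under *any* admissible ignore set counts as a
competitor. It admits a useful reduction — a candidate is in the level-$k$
union iff (its signature mismatches) + (missing positions) $\le k$ — which
makes the batch caller a handful of matrix comparisons and keeps the exact
semantics (tests verify equivalence against explicit subset enumeration).
With the reference panel's minimum pairwise signature distance of 3 over
7 markers, one erroneous call can never produce a wrong unique father.

## Estimating C

All assigned seeds of the eight plants of one maternal genotype in one block
(and year) form one unit of analysis: a two-column binomial response
(inter-genotype seeds, remaining seeds). The single-environment model is

$$\mathrm{logit}\, \pi = \mu + \mathrm{MG} + \mathrm{Block},$$

fitted by `stats::glm` with binomial family and logit link; with two years,
block is nested within year and the year $\times$ MG interaction enters. The
sequential analysis of deviance (`deviance_table`) adds terms in the order
given — the fit keeps the user's entry order (`keep.order = TRUE`; base R
would push interactions last) — and tests each change in deviance against
$\chi^2$. For the default design the null df is $64 - 1 = 63$ and the
residual df $49$. Overdispersion is reported as residual deviance (and
Pearson $\chi^2$) over residual df and flagged above 1.5.

## Estimating P and the 1/8 imputation

Markers cannot distinguish intra-genotype cross-fertilization from selfing.
The diagonal of each maternal cell's donor-count profile is therefore set to
the mean of the seven other donors' counts, raising the cell total by 1/7
and fixing the self-share at exactly 1/8 for every maternal genotype —
algebraically, whatever the counts. The imputation is applied **per
MG × block (× year) cell**: this is what yields the 512-row pair-level
dataset whose null df (511) and residual df after PG + MG + PG×MG + Block
(441) match the design arithmetic. (Applying it at coarser levels would
change those df; the cell level is the reading consistent with them.)

The pair-level response is (seeds sired by PG on that cell, the cell's
cross-fertilized total minus that). By construction the MG and Block main
effects carry (near-)zero deviance — the response is a composition within
each cell — and the mean P over donors is exactly 12.5% on the share scale.
Fractional imputed successes are **retained, not rounded**, and fitted as
weighted logistic responses: rounding would break the exact-1/8
construction. The likelihood is then a quasi-likelihood; since all reported
quantities are means and Wald/LR statistics this changes interpretation, not
arithmetic.

## LS means, contrasts, letters

LS means (`ls_means`) average the linear predictor with equal weights over a
complete grid of the other factors' levels, on the logit scale; standard
errors come from the coefficient covariance, intervals use the normal
multiplier 1.96 (Wald; whether the original analyses used normal or $t$
quantiles is not stated anywhere authoritative — normal is the standard GLM
choice), and means and intervals are back-transformed by the inverse logit.
Contrast families (`lsmean_contrasts`) are declared explicitly: optionally a
group contrast (e.g. inbred lines vs F1 hybrids as equal-weight group means)
plus all pairwise differences; the Bonferroni multiplier is the size of the
declared family and is recorded in the output. The compact letter display
uses insert-and-absorb, so two levels share a letter iff their adjusted
difference is not significant (checked against a maximal-clique oracle).
Genotype-level C and P means feed Pearson's product-moment correlation test
(`correlate_c_p`), for all genotypes and for the inbred-only subset.

## The synthetic-data generator: a stated world

The field data behind the method are not deposited, so the package carries a
first-class generator whose defaults *are* the reference conditions:

* 8 genotypes × 8 blocks × 8 single plants = 512 plants; 12 seeds sampled
  per plant (the "about 12" of practice, kept fixed for determinism);
* per-genotype cross-flower rate $X_g$ (default 0.5, the mid-range of
  reported faba bean outcrossing); a seed is cross-flower with probability
  $X_g$, otherwise selfed (autogamy and geitonogamy deliberately collapsed —
  no marker method separates them);
* cross-flower donor *genotype* sampled proportionally to donor weight ×
  mother–donor compatibility, own genotype included by default, so the
  expected intra share of cross events is 1/8 with equal weights — the
  estimator's imputation assumption can thus be stress-tested by simulating
  unequal weights;
* donor *plant* uniform within the genotype, excluding the mother: no
  spatial pollen kernel. The balanced-neighbourhood layouts these trials use
  are designed to make plants exchangeable, which is exactly this
  assumption;
* seeds are independent draws (no pod/ovule clustering);
* KASP-style call noise: each call missing with 0.02, otherwise one base
  substituted by the marker's other allele with 0.01 — rates chosen once as
  typical for a well-behaved KASP assay and matching the regime in which the
  resampling/omission rules matter.

The generator emulates genotype-specific mating behaviour and call noise; it
does **not** emulate pollinator foraging, spatial structure, flowering
phenology or seed abortion. A green recovery test therefore establishes that
the estimators are consistent for the generator's world, not that field
estimates are unbiased under spatially structured pollen flow.

The realized genetic C of a genotype has expectation $X_g(1 - s)$ with $s$
the intra share; recovery tests check that the GLM's 95% intervals cover
this in ≥ 93% of 100 seeded replicates. One known, accepted bias: erroneous
calls can only produce maternal mismatches on heterozygous (hence
preferentially inter-genotype) seeds, so the omission rule removes slightly
more cross- than self-fertilized seeds. At the default noise rates the
effect is well inside the intervals; it is a faithful desk analogue of the
field protocol, which omits the same seedlings.

## Marker-set selection

`minimal_distinguishing_set` finds the smallest marker subset on which all
candidate signatures are pairwise distinct, by exhaustive enumeration in
increasing size — exact at this scale (≤ 8 candidates, ≤ 20 markers) and
deterministic, ties broken lexicographically on sorted marker ids.
`select_validation_set` picks a disjoint second set that distinguishes on
its own; disjointness follows the marker arithmetic of the reference panels
(3 + 4 and 4 + 4). Only markers at which *every* candidate is homozygous are
eligible, so the same algorithm serves inbred lines and F1 hybrids. Two
extra confirmation markers, at which the F1s' parents carry different
alleles, verify hybridity (`confirm_f1_hybrid`).

## The founder-class inbreeding engine

`syngen` propagates inbreeding exactly. A population is a set of classes;
class $c$ has frequency and a matrix $J_c$ with $J_c[f,g]$ the probability
that its ordered allele pair descends from founders $f$ and $g$. Founders
are fully inbred and mutually unrelated, so IBD ⇔ same founder, and

* $F_c = \sum_f J_c[f,f]$, gamete marginal $p_c = (\text{row} +
  \text{col sums})/2$;
* selfing maps $J \mapsto (\mathrm{diag}(r + c) + J + J^\top)/4$, giving
  $F' = (1+F)/2$;
* crossing with pooled pollen marginal $\bar p$ gives $J' = p_c\,\bar p^\top$,
  and because $J$ is linear in the donor distribution, pooling donors
  (∝ frequency × pollen weight) is exact, not an approximation;
* coancestry between classes is $p_A \cdot p_B$; of an individual with
  itself, $(1+F)/2$.

With a single class and external unrelated pollen the engine's mean-$F$
trajectory equals the idealized recursion $F_{t+1} = (1-C)(1+F_t)/2$ exactly
(tested), whose fixed point is $(1-C)/(1+C)$.

**Scenario one** (equal P, $C = 0.5$, own genotype in the donor pool) gives
$\bar F_{\text{Syn-1}} = 9/16 = 0.5625$ and
$\bar F_{\text{Syn-2}} = 29/64 = 0.453125$, reproduced exactly by the
engine. **Scenario two** (seven lines with zero P; the sole siring line
receives only its own pollen and effectively selfs) yields the same Syn-1
value and reduces the population's mean genetic C by exactly 1/8 — both
emerge from the engine without special-casing, because a cross with a
genetically identical donor already produces a selfed-identical class.

Zero paternal success is carried by a single explicit locus (the seven null
founders); a class's pollen weight is its probability of being functional
under a recessive or dominant reading of the null. Both modes are exposed.
Under them the engine arrives at $\bar F_{\text{Syn-2}} = 0.513\overline{8}$
(recessive) and $0.5625$ (dominant); the published value 0.5967 for the
recessive reading could not be derived from the stated assumptions, and the
exact convention behind it is unknown — the engine documents its own
assumptions instead and does not treat that number as a target. The
qualitative conclusion — unequal P raises inbreeding from Syn-2 onwards —
holds under both modes and is asserted for generations 2–5.

One simplification: the pollen weight of a *mixture* class is its functional
fraction, while its contributed gamete uses the class marginal rather than
the marginal conditional on being functional. Through Syn-2 of the scenarios
all relevant classes are pure and the computation is exact; beyond that the
weights are a documented approximation.

## Numerical choices

* Class merging uses exact matrix equality to tolerance $10^{-12}$,
  preventing class blow-up across generations without affecting the dyadic
  scenario arithmetic (which is exact in floating point).
* Separation in a GLM is flagged at $|\mathrm{logit}| > 15$; affected LS
  means are reported with degenerate intervals and a warning rather than an
  error.
* Null df of a deviance table is defined as rows − 1 from the *dataset*, so
  empty (0, 0) cells keep the design-determined df; term and residual dfs
  then satisfy additivity by construction.
* All stochastic code takes one integer seed; the pipeline records seed and
  a config hash in every output directory, and identical config + seed give
  byte-identical TSVs (tested).

## Known limitations

* No spatial pollen dispersal, pollinator behaviour, or flowering-phenology
  model; block structure is represented but field-layout balancing is not
  computed.
* The paternity caller is combinatorial, not likelihood-based: genotyping
  error enters through the ignore budget, not an error model. Multi-allelic
  markers are out of scope.
* GLMs are fixed-effects only (no GLMM), corrections are Bonferroni only,
  and intervals are Wald.
* Field-scale results (per-genotype C of 28–63%, P of 4–25%, strongly
  negative C–P correlations) are not reproducible from code alone since the
  underlying data are not public; the package's claims are about the
  algorithms, verified against oracles and its own generator.
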