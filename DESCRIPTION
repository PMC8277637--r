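Package: polycrossr
Title: Paternity Assignment, Mating-System Estimation and Inbreeding
    Dynamics for Polycross Nurseries
Version: 0.1.0
Authors@R:
    person("Polycross", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for SNP-based analysis of mixed mating systems in
    polycross nurseries of partially allogamous crops such as faba bean
    (Vicia faba). Provides a synthetic polycross generator (layout, mating
    events with genotype-specific cross-fertilization rates and pollen-donor
    weights, Mendelian transmission with genotyping-call noise), an exact
    mismatch-tolerant paternity caller for homozygous candidate parents,
    binomial-logit GLM estimation of the degree of cross-fertilization (C)
    and of paternal outcrossing success (P) with the 1/8 intra-genotype
    imputation, sequential analysis-of-deviance tables, least-square means
    with Bonferroni-adjusted contrasts and compact letter displays, and an
    exact founder-class engine for inbreeding dynamics of synthetic
    cultivars across Syn generations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
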