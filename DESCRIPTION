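Package: kinliab
Title: Offspring-of-Siblings Liability-Threshold Models for
    Intergenerational Transmission of Suicidal Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the intergenerational transmission of a
    binary phenotype (suicidal behavior) with multi-generation registry
    data and kinship-informed designs.  Implements a two-generation
    liability-threshold ACE structural model with a direct parent-to-
    offspring transmission path and a cross-generation genetic
    correlation, fitted by maximum likelihood on extended families of
    same-sex sibling parents and their offspring; a moment solver over
    relationship-specific tetrachoric correlations; propensity score
    construction; Kaplan-Meier and population plus within-cousin-pair
    (stratified, cluster-robust) Cox proportional hazards models; a
    seeded synthetic multi-generation registry generator with known
    ground truth; and a reproducible pipeline that chains the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    numDeriv,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
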