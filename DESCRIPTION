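Package: somarch
Title: Functional Connectivity Archetypes via Stability-Tuned Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers archetypal resting-state functional-connectivity profiles by
    clustering per-run connectomes with self-organizing maps (SOMs) whose grid size and
    training length are tuned for clustering stability (adjusted Rand index and adjusted
    mutual information), consolidated by consensus clustering over repeated runs. The
    archetypes' 2D grid coordinates then enter a two-way ANOVA / linear mixed-effects
    association battery against behavioral scores, with restricted post-hoc comparisons
    and FDR/Bonferroni control, to detect degenerate brain-behavior coding, that is,
    connectionally distant archetypes that share the same behavioral outcome. Includes a
    synthetic connectome generator with planted grid-archetype structure and known
    behavioral coding for end-to-end validation, principal-component reduction with Monte
    Carlo (Horn) parallel analysis, and a Monte Carlo null for within-subject assignment
    consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    car,
    lme4,
    lmerTest,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    withr
Config/testthat/edition: 3
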