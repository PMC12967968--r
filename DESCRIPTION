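Package: neutroscore
Title: Neutrosophic Scoring of Stereotactic Surgical Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores stereotactic surgical attempts with a single-valued
    neutrosophic model. Each attempt is summarised by its Euclidean
    deviation from the target (mm) and a scalar motor-instability
    measure; three membership functions (Truth, Indeterminacy, Falsity)
    map the pair to a bounded competence score S = (2 + T - I - F)/3.
    Includes kinematic helpers that derive the two inputs from raw tip
    coordinates and trajectories, a seeded three-class cohort simulator
    with Gaussian class priors, a nonparametric validation pipeline
    (Shapiro-Wilk, tie-corrected Kruskal-Wallis, Dunn post-hoc with
    Bonferroni correction), competence-landscape and decision-region
    grids, a classical distance-threshold comparator with a discordance
    audit, and a command-line interface for end-to-end reproduction.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
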