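Package: itvtools
Title: Intraspecific Trait Variation Analysis with Variance-Ratio Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intraspecific functional trait variation
    across populations and ontogenetic stages. Provides a validated tidy
    trait-table format, assumption-driven selection of location tests
    (ANOVA, Welch ANOVA, t-test, Welch t-test, Mann-Whitney U), a
    dummy-coded two-factor linear model with interaction, standardized
    principal component analysis, and an external-filtering analysis based
    on the T-statistic T_IP.IR (the ratio of a population's trait variance
    to the regional pool's variance at the individual level) with
    label-permutation null models, standardized effect sizes, and two
    one-sided empirical tests. A synthetic-data generator with a null-world
    mode and a variance-filtering knob makes every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    car,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
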