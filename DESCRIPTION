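Package: lipidsce
Title: Membrane Stored Curvature Elastic Stress Estimates from Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates membrane stored curvature elastic (SCE) stress from
    species-level lipidomic quantification tables. Converts integrated LC-MS
    peak areas to absolute amounts via class-matched internal standards,
    derives head-group and acyl-chain compositions, computes the lipid
    contribution to SCE stress through an ideal-additive-mixing spontaneous
    curvature model, and computes the dimensionless P_SCE proxy of total
    cellular SCE stress via a weighted ratio control function with a
    pivot-lipid classification. Includes a synthetic choline-rescue
    time-course generator for validation, sensitivity-analysis helpers, and
    the group statistics (one-way ANOVA with Bonferroni correction, pooled
    two-sample t tests) used for reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
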