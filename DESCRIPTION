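Package: mrmediate
Title: Two-Sample Mendelian Randomization and Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) from GWAS summary
    statistics, oriented at exposure-mediator-outcome questions such as the
    gut microbiota -> blood metabolite -> chronic gastritis pathway.
    Provides harmonization of exposure and outcome associations to a common
    effect allele, instrument selection (p-value screening, greedy LD
    clumping, F-statistic and Steiger directionality filtering), a suite of
    causal estimators (inverse-variance weighted, MR-Egger, weighted median,
    robust adjusted profile score), sensitivity diagnostics (Cochran's Q,
    funnel data, leave-one-out, MR-PRESSO), MR power calculation, and
    two-step mediation decomposition with delta-method confidence
    intervals. Includes a summary-level simulator of
    exposure-mediator-outcome GWAS triplets with known ground truth for
    method validation, and tidy() / glance() methods plus ggplot2 helpers
    for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
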