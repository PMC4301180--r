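Package: cryomoss
Title: Time-Series Cold-Response Transcriptome Analysis for Moss Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for time-series cold-stress transcriptome
    experiments in the moss Physcomitrella patens and comparable designs:
    median normalization and per-gene K-groups ANOVA with Benjamini-Hochberg
    false discovery rate control, Tukey HSD pairwise post-hoc tests with
    per-gene Bonferroni correction, fold-change effect sizes and persistence
    calls; Fisher's exact over/under-representation of annotation terms and
    early/intermediate/late stage partitioning; enrichment analysis of orphan
    (species-specific) genes by response stage and direction; comparative
    classification of transcription-associated protein (TAP) families into
    developmental versus stimulus/stress process classes with tiered quality
    classes; and Gaussian generalized linear models of log2 fold changes for
    class- and family-level regulatory trends. Includes a seeded synthetic-data
    generator that emulates the 5 time point x 3 replicate microarray design
    with planted effects, so the whole chain is testable without external data.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
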