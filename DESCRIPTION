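Package: tocointake
Title: Dietary Tocopherol and Tocotrienol Intake Assessment from Food
    Frequency Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes daily dietary intake of the eight vitamin E isoforms
    (alpha-, beta-, gamma-, delta-tocopherols and -tocotrienols) from
    semiquantitative food frequency questionnaire (FFQ) responses scored
    against a food composition database, converts intakes to alpha-tocopherol
    equivalents, classifies adequacy against dietary reference intake
    frameworks (NIPH-NIH-NRI, NIH, EFSA), and quantifies agreement between
    two dietary assessment methods with Bland-Altman limits-of-agreement
    analysis, Spearman rank correlation, and the Mann-Whitney U test. Includes
    a built-in 41-item vitamin E FFQ instrument and a synthetic-cohort
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
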