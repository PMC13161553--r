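Package: feedenergy
Title: Feed Energy Evaluation for Growing Pigs from Balance Trials and
    In Vitro Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for the energetic evaluation of swine feed
    ingredients. Computes diet-level digestible and metabolizable energy
    (DE, ME) from total-collection balance records, ingredient-level
    energies by the direct and substitution (difference) methods,
    blank-corrected in vitro digestible energy (IVDE) from digestion-tube
    records, linear calibrations of DE and ME on IVDE with mean-response
    confidence intervals and coefficient tests, and additivity/agreement
    validation of predicted energies in mixed diets. Ships transcribed
    reference tables from a 20-ingredient growing-pig digestibility study
    and a synthetic-study generator (Youden-square balance design,
    replicated in vitro runs) so every stage is testable end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
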