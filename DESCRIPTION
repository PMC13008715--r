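Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event reports. Reads quarterly '$'-delimited or
    CSV report tables, deduplicates cases by the most-recent-receipt rule, builds
    primary-suspect cohorts with drug-name normalization and PT-to-SOC coding, and
    screens drug-event pairs with four disproportionality statistics (reporting odds
    ratio, proportional reporting ratio, the Bayesian confidence propagation neural
    network information component, and a closed-form empirical Bayes geometric mean)
    under a two-of-four consensus rule. Also provides time-to-onset binning and
    summaries, demographic and sex-stratified (volcano) summaries, label-novelty
    assessment, and a seeded synthetic report generator with planted signals for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
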