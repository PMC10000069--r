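Package: sevband
Title: Banded Severity Scoring for Laboratory Animal Welfare Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the severity ('suffering') experienced by
    animals in subacute and chronic experiments from routinely measured
    clinical criteria. Deviations of each criterion from a per-animal or
    control baseline are assigned to one of five ordinal bands (normal, mild,
    moderate, severe, beyond severe or death), aggregated into group
    criterion averages, overall impact scores and per-animal average impact,
    and compared against individual severity limits and predicted project
    severity classifications, supporting both prospective humane-endpoint
    alerting and retrospective actual-severity reporting. Includes a
    synthetic cohort generator with configurable band occupancy
    probabilities, CSV/YAML input-output, a JSON assessment report and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
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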