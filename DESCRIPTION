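Package: irregbin
Title: Bin-Based Diagnostics for Visit Irregularity in Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Descriptive measures of visit irregularity for longitudinal
    studies with irregular, potentially informative observation times.
    Divides the study period into bins (anchored on protocol visit times or
    tiling the follow-up window) and summarises the mean proportions of
    individuals with 0, 1, and more than 1 visit per bin, with an at-risk
    adjustment for staggered entry and administrative censoring. Provides
    bin-width sweeps, a repeated-measures versus irregular-visits
    classification rule, and an area-under-the-curve irregularity score.
    Includes a visit-process simulator (perfect repeated measures, per-visit
    missingness, schedule jitter, and history-dependent counting-process
    intensities) and an Andersen-Gill visit-intensity workflow producing
    inverse-intensity weights for downstream outcome analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
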