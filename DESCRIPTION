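Package: connectogrip
Title: Sensorimotor Network Connectivity and Hand Grip Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking structural brain connectivity to
    distinct aspects of hand grip performance in hemiparetic cohorts.
    Extracts five grip performance measures (strength, reaction time,
    relaxation time, force magnitude control, force direction control)
    from three-axis digit force recordings; builds symmetric,
    distance- and volume-corrected connectivity matrices from
    tractography streamline counts over a 20-region sensorimotor set;
    identifies latent networks by a two-level exploratory factor
    analysis of connectome edges; and quantifies network-performance
    associations while controlling for regional lesion load. Includes
    a fully seeded synthetic-cohort generator with planted ground
    truth so every stage is testable without clinical data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
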