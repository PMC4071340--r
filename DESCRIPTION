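Package: netdosage
Title: Network-Dosage Compensation in Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing network-dosage compensation in gene
    regulatory networks. Implements steady-state and dosage-sensitivity
    theory for N-component networks under a shared transcriptional
    centre, ODE-based inducibility curves for two-component
    activator-inhibitor topologies, compensation and inducibility
    penalty metrics with Monte-Carlo parameter sweeps, and a
    genome-scale motif search for potentially compensated units (PCUs)
    from transcription-factor binding, physical-interaction and
    genetic-interaction tables. Includes a seed-controlled synthetic
    interaction-data generator with planted motifs for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
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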