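Package: replicycle
Title: Bacterial Cell-Cycle Parameter Inference from Marker-Frequency and
    Replication Run-Out Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers bacterial replication-cycle parameters under the
    Cooper-Helmstetter steady-state model. Estimates the C period
    (replication elongation time) from qPCR marker-frequency data via
    Pfaffl relative quantification of the oriC-to-ter ratio, the D period
    (termination-to-division time) from origins per cell measured by
    replication run-out flow cytometry, and the age and cell size at
    replication initiation from the uninitiated fraction of run-out DNA
    histograms mapped through the steady-state exponential age
    distribution. Includes constrained Gaussian-mixture decomposition of
    run-out histograms into integer-chromosome classes, DnaA-per-origin
    accounting from quantitative immunoblots and hemocytometer counts,
    and a forward simulator of steady-state multifork-replicating
    populations so the full analysis chain is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
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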