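Package: barriertools
Title: Analytics for In Vitro Blood-Brain Barrier Transwell Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw Transwell plate-reader tables from in vitro
    blood-brain barrier models into endothelial permeability coefficients
    and downstream endpoints. Implements clearance-slope PS fitting with
    series-resistance filter correction, temperature-based
    paracellular/transcellular pathway decomposition, apparent
    permeability (Papp) and inulin-referenced transcytosis quotients for
    bidirectional amyloid-beta transport, delta-delta-Ct relative qPCR
    quantification, MTT viability, Western densitometry normalization,
    immunofluorescence area-fraction quantification with nuclei counting,
    and the matching group statistics (exact Mann-Whitney U, unpaired t,
    SEM summaries, significance stars). A deterministic synthetic assay
    generator forward-simulates every supported assay with known ground
    truth so the whole pipeline is testable without laboratory data.
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
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
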