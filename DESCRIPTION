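Package: cyanospike
Title: Detection and Summary of Bioelectric Events in Cyanobacterial
    Extracellular Voltage Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extracellular voltage traces recorded from
    cyanobacterial (Oscillatoria sp.) biofilms on planar microelectrodes
    during nitrogen starvation and ammonium repletion. Separates raw traces
    into a fast band for millisecond spike detection (robust MAD-based
    thresholding with refractory merging) and a slow band for segmentation
    of random-telegraph-signal (RTS) two-state fluctuations (equal-variance
    Gaussian mixture with minimum-dwell enforcement), and summarises the
    result as per-minute event rates and amplitude quartiles per recording
    day. Includes a seeded synthetic-trace generator calibrated to the
    six-day starvation/repletion course, strict CSV/JSON trace and event
    I/O, a one-command pipeline with a reproducibility manifest, and
    ggplot2 visualisations.
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
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
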