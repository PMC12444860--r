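Package: phagopulse
Title: Ring-Fluorescence Quantification and Pulse Detection on Tracked Phagosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies reporter recruitment to phagosome membranes in 3D
    time-lapse fluorescence movies: intensity-based volumetric segmentation,
    phagosome tracking (built-in linker or TrackMate XML import), annular
    angular intensity profiles ("ring fluorescence" kymographs), low-pass
    filtering, per-track min-max normalisation and time-zero alignment, and a
    deterministic pulse detector that operationalises pulsatile reporter
    re-recruitment. Includes a ground-truthed synthetic 4D movie generator
    emulating neutrophils bearing bacteria-containing phagosomes (closure
    surge, exponential fade, scheduled pulses, transient re-opening, dye
    influx, pH-dependent prey brightness, camera noise) plus cohort-level
    statistics: per-neutrophil pulsing fractions, first-pulse latency,
    burden correlations, dye-accumulation classification, peri-bacterial
    shell ratios, and exact binomial event tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tiff,
    utils,
    withr,
    xml2,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
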