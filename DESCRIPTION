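Package: aviphen
Title: Metabolic and Behavioral Phenotyping of Birds from Multiplexed
    Respirometry and Load-Cell Biomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for live-in avian metabolic phenotyping:
    corrections for multiplexed flow-through (pull) respirometry
    (lag alignment, instantaneous z-transform washout correction,
    stable-window extraction, baseline interpolation, water-vapor
    dilution correction and gas-exchange equations), Weir energy
    expenditure and daily minimum metabolic rate summaries, denoising
    and event classification for 1 Hz load-cell records of perch, food
    and water mass (rolling statistics, minimum-SD point selection,
    error-propagated differencing, 3-SD outlier rejection, refill and
    body-mass recode rules), hourly phenotype tables with AIC-based
    linear-model selection, and a bird-in-chamber simulator that
    generates ground-truthed gas traces, load-cell logs and RFID
    body-temperature reads for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
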