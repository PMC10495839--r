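Package: capstall
Title: Semi-Automated Detection and Analysis of Capillary Stalling in
    Angiographic Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting transient interruptions of red blood cell
    flow (stalls) in cortical capillaries imaged as 2D+time fluorescence
    angiograms. Provides a synthetic angiogram simulator with exact ground
    truth, Hessian-based vessel enhancement and centerline graph extraction,
    motion-stabilized length-time (kymograph) extraction, frame-to-frame
    correlation thresholding to flag stall events, stallogram summary
    statistics (incidence, point prevalence, cumulative stall duration),
    duration filtering and exponential incidence-accumulation model fitting,
    validation truth tables, and arteriole diameter / dilation-triggered
    stall prevalence analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
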