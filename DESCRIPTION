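Package: hentherm
Title: Thermographic Detection and Monitoring of Laying Hens
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of laying hens in grey-scale thermographic frames by
    adaptive background thresholding and rotation-aware normalized
    cross-correlation template matching, with a colored-pixel fallback rule.
    Provides the full monitoring pipeline of a ceiling-mounted infrared
    sensor: frame input/output with an intensity-temperature calibration,
    histogram-based floor temperature estimation, binarization and particle
    filtering, elliptical and triangular hen templates with geometry
    calibration from annotated frames, slot-based monitoring with text logs,
    confusion-matrix evaluation (sensitivity, specificity, error rate,
    accuracy), and a synthetic thermal-scene generator with ground truth for
    benchmarking every stage without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    tools,
    stats,
    utils,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
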