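Package: emtrecon
Title: Electromagnetic-Tracking Based Implant Reconstruction for HDR
    Prostate Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to turn step-and-shoot electromagnetic tracking (EMT)
    measurements of implanted brachytherapy needles into a registered,
    dwell-position-bearing DICOM RT plan for intraoperative high-dose-rate
    (HDR) prostate brachytherapy.  Includes rigid 6DoF coordinate
    registration (reference-sensor and point-correspondence workflows),
    cubic-spline needle path reconstruction with arc-length parameterized
    dwell placement, a minimal DICOM RT Plan / RT Structure Set reader and
    writer, a TG-43 style point-source dose engine with dose-volume
    histogram metrics, reconstruction comparison statistics (per-dwell
    Euclidean distances, k = 2 reproducibility, paired significance tests),
    and a synthetic phantom simulator that replaces the clinical tracking
    hardware for testing and method studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
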