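Package: phantomcal
Title: Phantom-Based CT Density Calibration and Periprosthetic Bone Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative computed-tomography densitometry with an
    in-house density calibration phantom (DCP). Fits per-scan linear
    intensity-to-density calibration lines from polymer insert scans, maps CT
    volumes to real density (g/cc), and quantifies periprosthetic bone changes
    across total hip arthroplasty stages (pre-surgery, post-broaching,
    post-implantation): rigid registration, Gruen-zone and bone-implant
    interface regions of interest, bone volume fraction (BV/TV), and
    scan-parameter sensitivity analysis. Includes a synthetic micro-CT
    generator (phantom, femur, surgical stages, partial-volume medical-CT
    analogue) with known ground truth so the full pipeline is testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    tiff,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
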