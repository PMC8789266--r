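Package: dentomark
Title: Automated Tooth Landmarking and Occlusal Scoring on Dental Arch Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fully automated landmark recognition on triangle-mesh scans of
    single dental arches: anatomical orientation by principal component
    analysis with a tooth-tip plane refinement, occlusal peak-point detection,
    curvature-bounded tooth partitioning with a spill rule and quadratic
    jawline merging, template-constrained tooth assignment by dynamic
    programming against a labelled training set, and cusp landmark extraction.
    Includes the modified Huddart-Bodenham (MHB) occlusal index computed from
    a registered maxillary/mandibular pair via a mandibular cubic spline and a
    least-squares reference plane, a deterministic implicit-surface generator
    of synthetic dental arches with full ground truth, and validation metrics
    (per-tooth outcome categories and landmark deviation statistics with
    geometric-mean confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    generics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
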