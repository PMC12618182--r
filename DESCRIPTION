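Package: ctiq
Title: Automated Task-Based CT Image Quality and Detectability Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of task-based image quality from CT
    phantom image stacks. Locates an ACR-464-style phantom and its four
    material inserts, estimates the task-transfer function (TTF) from
    logistic fits to radially sampled edge-spread functions, estimates the
    2D and radially averaged 1D noise power spectrum (NPS) from square ROIs
    in a homogeneous module, builds circular task functions (flat and
    Gaussian profiles), and computes the non-pre-whitening (NPW) model
    observer detectability index d-prime, with eye-filter (NPWE) and
    internal-noise (NPWi) variants and synthetic nodule-image rendering.
    Includes a phantom simulator with configurable system blur, noise
    magnitude and noise colour so that every estimator can be validated
    against known ground truth, plus a minimal single-frame CT DICOM
    reader/writer and parameter-sweep runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    minpack.lm,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
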