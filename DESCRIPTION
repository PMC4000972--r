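Package: gaborgist
Title: Video Classification of Normal and Abnormal Patient Movement with
    Spatiotemporal Gabor Gist Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies short video clips of bedridden patients as showing
    normal or abnormal (seizure-related) movement. Clips are converted to
    grayscale intensity volumes, filtered with a bank of four spatiotemporal
    3D Gabor filters (one scale, four orientations), pooled over a 4x4x4
    spatiotemporal grid into a 256-dimensional gist descriptor, and
    classified with a soft-margin support vector machine solved by
    sequential minimal optimization. Includes the repeated per-patient
    half-split evaluation protocol and a synthetic video generator that
    emulates smooth normal motion versus abrupt direction reversals with
    frozen periods, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
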