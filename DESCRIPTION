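Package: swimkin
Title: Undulatory Swimming Kinematics from Video Silhouettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of anguilliform (eel-like) swimming from
    silhouette video: midline (centerline) tracking from binary or grayscale
    frame stacks, traveling-body-wave parameter estimation (tail-beat
    frequency, wavelength, amplitude envelope, wave speed), propulsive
    efficiency surrogates (Strouhal number, stride length), and the
    statistical comparisons used in functional-recovery studies of
    spinal-transected swimmers (one-way ANOVA with Holm-Sidak post hoc
    tests, regressions on percent axon regeneration, and a random-intercept
    mixed model of speed on tail-beat frequency). Includes a synthetic
    anguilliform swimmer generator that renders silhouette frame stacks with
    known ground truth, so the whole pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    nlme,
    car,
    stats,
    utils,
    tiff,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
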