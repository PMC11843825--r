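Package: burndyn
Title: Model-Based Hyperspectral Analysis of Burn Wound Perfusion Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based analysis of hyperspectral burn-wound images:
    a six-layer skin perfusion forward model and approximate inverse solver
    recovering per-pixel perfusion profiles (hemoglobin volume and oxygen
    saturation per layer) from remission spectra, secondary perfusion indices
    (flow and oxygen-consumption rates) projected into two 2D parameter spaces,
    homogeneity-based wound segmentation, a healing-time clinical reference
    classification, per-day kernel-density class regions with convex-hull
    abstraction and overlap metrics, a preliminary region-membership burn-class
    estimator, and a synthetic cohort generator emulating class-specific wound
    dynamics over days 0-3 post-burn.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, tools, yaml, jsonlite, png
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
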