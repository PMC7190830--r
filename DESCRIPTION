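Package: wormnav
Title: Worm Tracking and Salt-Chemotaxis Navigation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of Caenorhabditis elegans salt-chemotaxis
    behavior on linear NaCl gradients: centroid tracking of dark worms on
    bright arenas (average-background subtraction, Gaussian smoothing,
    size-gated blob detection, nearest-neighbor linking), rule-based
    behavioral-state segmentation (run, pause, turn, pirouette), per-animal
    navigation indices (chemotactic, biased-random-walk and klinotaxis),
    roaming/dwelling classification on food, calcium-trace normalization
    (dF/F0 and ratiometric dR/R) and four-parameter-logistic EC50 fitting
    for GPCR concentration-response assays. A run-and-tumble simulator with
    controllable directional biases, a frame renderer and calcium and
    dose-response generators provide fully synthetic inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
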