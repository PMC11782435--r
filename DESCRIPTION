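Package: osteoimpact
Title: Impact-Hammer Force Signal Analysis for Detecting Osteotome Crossing of Bone Plates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of instrumented-mallet force signals recorded during
    osteotomies of thin bone plates. Extracts per-impact indicators from the
    first two peaks of each force trace (the inter-peak delay tau and the
    Gaussian peak-area ratio lambda), models the piecewise-linear dependence
    of tau on plate thickness with a Nelder-Mead fit, and classifies impacts
    as 'Bone' or 'Crossing' with a cost-sensitive soft-margin linear support
    vector machine whose misclassification cost matrix is tuned by minimizing
    the negative likelihood ratio. Includes a seeded phenomenological
    generator of synthetic osteotomy experiments and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
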