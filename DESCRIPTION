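Package: ecvagree
Title: Physical-Consistency Agreement Analysis for Paired Vegetation ECV Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assesses the physical consistency between two linked terrestrial
    Essential Climate Variable (ECV) products, such as Leaf Area Index (LAI)
    and the Fraction of Absorbed Photosynthetically Active Radiation (FAPAR),
    by classifying simultaneous temporal changes with per-observation
    uncertainties. Each consecutive change receives a confidence level from
    the non-overlap of the two value-plus-uncertainty intervals and is
    classified as increase, decrease, or non-significant; simultaneous class
    pairs are tabulated into a 3x3 contingency table from which overall
    agreement, Dice-coefficient sensitivities, and non-coherence and
    non-significance biases are derived. Includes per-time-step (regional)
    and per-pixel consistency analyses with monthly climatologies, seasonal
    Mann-Kendall trend tests and Welch/Kolmogorov-Smirnov product
    comparisons, confidence-threshold sensitivity sweeps, inverse-variance
    weighted spatial aggregation with propagated uncertainty, land-cover
    majority resampling, and a synthetic paired-product generator for
    end-to-end validation without satellite archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
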