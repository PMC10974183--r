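Package: raytox
Title: Mixture Toxicity Analysis for Fixed-Ratio Ray Designs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Concentration-response analysis for binary (and m-ary) chemical
    mixtures tested with the fixed concentration ratio ray method on algal
    growth-inhibition assays. Fits two-parameter Weibull and Hill
    concentration-response curves by least squares, selects the better model
    by R2/RMSE, and computes effect concentrations with 95 percent observed
    confidence intervals by nonparametric bootstrap. Predicts mixture
    toxicity under the concentration addition and independent action
    reference models, classifies interactions (additive, synergism,
    antagonism) with the mixture deviation ratio and its confidence bounds,
    and computes dose reduction indices. Includes spectrophotometric
    endpoint calculators (growth inhibition from optical density,
    malondialdehyde, chlorophyll a/b, carotenoids, relative change versus
    control, Pearson correlation panels) and seeded synthetic plate-data
    generators so the full pipeline can be exercised without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
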