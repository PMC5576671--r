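Package: seastab
Title: Seasonal Stability of Seagrass Fish Communities Under Marine Protection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to ask whether marine protected areas (MPAs) buffer
    monsoon-driven seasonal variability in seagrass-associated fish
    communities. Provides a survey data model for belt-transect underwater
    visual census data, a negative-binomial community simulator with
    seasonal forcing, seagrass-cover mediation and management-dependent
    synchronous perturbations, univariate mixed-model analyses (likelihood
    ratio tests, marginal/conditional R-squared, Tukey all-pair contrasts,
    variance inflation factors), multivariate community analyses
    (Bray-Curtis dissimilarity, strata-constrained PERMANOVA, SIMPER,
    non-metric multidimensional scaling), ordination-trajectory temporal
    stability metrics (area, range, mean distance to centroid, mean
    distance between consecutive points), piecewise structural equation
    models with d-separation basis sets and Fisher's C, and pairwise
    species-density synchrony analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    optparse,
    withr
Config/testthat/edition: 3
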