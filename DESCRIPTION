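Package: chinookdiet
Title: Diet Composition and Bioenergetics Scores from Juvenile Salmon Stomach Contents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stomach-content data from juvenile
    (subyearling) Chinook salmon sampled in tidal-wetland monitoring
    programmes. Computes prey-importance indices (percent numeric and
    gravimetric composition, frequency of occurrence, Index of Relative
    Importance), per-fish foraging scores (instantaneous ration, energy
    ration, temperature-dependent maintenance metabolism), multivariate
    diet comparisons among sites, years and fish size classes
    (Bray-Curtis dissimilarity, non-metric multidimensional scaling,
    ANOSIM, SIMPER, species-vector fitting), and gamma log-link
    regressions of the foraging scores with estimated marginal means,
    pairwise contrasts and Cohen's d effect sizes. Includes a seeded
    synthetic-data generator that emulates a five-site, February-July
    estuarine sampling design for testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    emmeans,
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
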