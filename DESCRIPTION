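Package: benthoscape
Title: Substrate Classification and Map-Error Assessment on Synthetic Seafloors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-class seafloor substrate classification and its
    evaluation. Generates seeded synthetic shelf bathymetries with known
    substrate truth, derives the standard benthic-terrain predictor suite
    (slope, curvature, rugosity, multi-scale bathymetric position indices,
    wind fetch, resampled energy fields), fits prevalence-weighted random
    forest classifiers at multiple grid resolutions, and assesses the
    resulting maps with a comprehensive metric set: overall accuracy,
    multi-category true skill statistic, per-class user/producer accuracy and
    true negative rate, the quantity/exchange/shift disagreement
    decomposition, class imbalance, and no-information baselines. Includes an
    experiment driver for weighting, resolution, depth-zone, and
    independent-data comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
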