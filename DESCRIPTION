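Package: cdsrs
Title: Customized Deep Sleep Recommender System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clusters wearable sleep-sensor features (sleep time, movement,
    sound, snoring, BMI) into sleep-pattern labels with K-means (cluster count
    chosen by elbow curve plus silhouette validation), builds a sparse user by
    pattern rating matrix, predicts ratings by similarity-weighted averaging
    within pattern groups, serves top-N recommendations with a k-nearest-
    neighbour fallback for cold-start users, and improves recommendations
    through a simulated feedback loop.  Includes a synthetic motion-bed data
    generator with known ground truth, collaborative and content-based
    filtering baselines, and an MSE/MAPE evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
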