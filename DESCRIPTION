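Package: swimbout
Title: Burst-Glide Swim Bout Analysis, Visual Assay Statistics, and Ocular
    Biometry for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies larval zebrafish locomotor behaviour and ocular
    biometry from plate-based video-tracking exports. Classifies swim speeds
    into inactive, coast, and burst activity classes, segments bouts, bins
    activity, applies a three-step normalization (well illumination, batch,
    baseline), and computes response statistics for visual motor response
    (VMR), flash-stimulus threshold response (FSTR), free-swim, and
    colour-maze assays. Derives ocular metrics (lens ratio, normalized axial
    length, relative refractive error) and morphometric ratios, and provides
    resampling statistics: bootstrap mean-difference estimation, rank-sum
    tests, and efficiency-corrected relative expression ratios with a
    randomization test. Includes a stochastic burst-glide locomotion
    simulator that generates synthetic traces, biometry, morphometry, Ct
    tables, and colour-maze counts for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
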