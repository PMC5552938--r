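Package: spotmatch
Title: Photo-Identification Matching Algorithms and Rank-Based
    Recognition Evaluation for Capture-Recapture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking natural-marking photo-identification
    pipelines for photographic capture-recapture studies. Implements two
    pixel-based similarity scores (part-wise sum-of-absolute-differences
    maximized over a scale/translation search, and patch-grid normalized
    cross-correlation template matching), two feature-based scores
    (descriptor matching with geometric verification, and
    keypoint-location-only robust affine matching), the preprocessing chain
    used for elongate amphibians (spine straightening, cropping,
    binarization, 4x4 block downscaling), and a rank-based evaluation
    framework (rank cumulative match curves, false rejection rates,
    database-size subsampling, multi-match recognition, and a
    manual-versus-computer-aided processing-time cost model). A synthetic
    spot-pattern generator with known ground truth emulates strip- and
    belly-type amphibian pattern databases so the whole pipeline can be
    exercised end to end without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    utils,
    stats,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
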