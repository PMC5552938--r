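#' Matcher objects for database-wide scoring
#'
#' A matcher bundles a per-image preparation step with a pairwise scoring
#' function so that [all_pairs_scores()] prepares every image exactly once.
#' Four matchers cover the two pixel-based and two feature-based scoring
#' schemes:
#'
#' * `matcher_sad()` — 4x block-downscales each pattern, then part-wise SAD
#'   similarity ([sad_similarity()]).
#' * `matcher_itm()` — full-resolution patch-grid template matching
#'   ([itm_similarity()]); `"binary"` mode Otsu-binarizes each pattern first.
#' * `matcher_feature_geo()` — descriptor detection plus
#'   [geometric_match_score()].
#' * `matcher_feature_points()` — binarization, blob keypoints, and
#'   [point_affine_score()].
#'
#' @param cfg The matching configuration object for the underlying score.
#' @param detector Detector passed to [detect_features()].
#' @param binarize_polarity Polarity used when a matcher binarizes
#'   internally (dark spots on a light background by default).
#' @return A `pattern_matcher` object with elements `name`, `prepare(pattern)`
#'   and `score(rep_a, rep_b)`.
#' @name matchers
NULL

new_matcher <- function(name, prepare, score) {
  structure(list(name = name, prepare = prepare, score = score),
            class = "pattern_matcher")
}

#' @export
print.pattern_matcher <- function(x, ...) {
  cat(sprintf("<pattern_matcher: %s>\n", x$name))
  invisible(x)
}

#' @rdname matchers
#' @export
matcher_sad <- function(cfg = sad_config()) {
  new_matcher("sad",
              prepare = function(pattern) downscale_quarter(pattern),
              score = function(a, b) as.numeric(sad_similarity(a, b, cfg)))
}

#' @rdname matchers
#' @export
matcher_itm <- function(cfg = itm_config(),
                        binarize_polarity = c("dark_fg", "light_fg")) {
  binarize_polarity <- match.arg(binarize_polarity)
  prepare <- if (cfg$mode == "binary") {
    function(pattern) binarize(pattern, "otsu", polarity = binarize_polarity)
  } else {
    function(pattern) pattern
  }
  new_matcher(paste0("itm-", cfg$mode),
              prepare = prepare,
              score = function(a, b) as.numeric(itm_similarity(a, b, cfg)))
}

#' @rdname matchers
#' @export
matcher_feature_geo <- function(cfg = geo_match_config(),
                                detector = "si_descriptor") {
  new_matcher("feature-geo",
              prepare = function(pattern) detect_features(pattern, detector),
              score = function(a, b) as.numeric(geometric_match_score(a, b, cfg)))
}

#' @rdname matchers
#' @export
matcher_feature_points <- function(cfg = point_match_config(),
                                   detector = "blob_binary",
                                   binarize_polarity = c("dark_fg", "light_fg")) {
  binarize_polarity <- match.arg(binarize_polarity)
  new_matcher("feature-points",
              prepare = function(pattern) {
                p <- if (is_binary_pattern(pattern)) pattern
                     else binarize(pattern, "otsu", polarity = binarize_polarity)
                detect_features(p, detector)
              },
              score = function(a, b) as.numeric(point_affine_score(a, b, cfg)))
}
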