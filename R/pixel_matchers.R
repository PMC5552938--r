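#' Configuration for the part-wise SAD matcher
#'
#' The SAD matcher partitions the (already 4x-downscaled) query pattern into
#' a grid of parts; each part is compared against candidate regions of the
#' other pattern produced by every combination of scale and integer
#' translation in the search grid, and keeps the best candidate. Defaults
#' cover the crop/scale jitter typical of field photographs while bounding
#' search cost.
#'
#' @param parts_rows,parts_cols Part grid (remainder pixels go to the last
#'   row/column of parts).
#' @param scales Scale factors to search; must include 1.
#' @param max_translation Translation search radius in downscaled pixels
#'   (step 1, per part).
#' @param min_overlap_fraction Candidates whose in-bounds overlap with the
#'   other pattern falls below this fraction are skipped.
#' @param max_intensity Intensity normalization constant (8-bit: 255).
#' @param per_part If `TRUE` (default) each part keeps its own best
#'   transform; if `FALSE` one shared transform is maximized globally.
#' @return A `sad_config` object.
#' @export
sad_config <- function(parts_rows = 2, parts_cols = 7,
                       scales = c(0.90, 0.95, 1.00, 1.05, 1.10),
                       max_translation = 6, min_overlap_fraction = 0.5,
                       max_intensity = 255, per_part = TRUE) {
  check_number(parts_rows, "parts_rows", min = 1)
  check_number(parts_cols, "parts_cols", min = 1)
  if (length(scales) == 0 || !any(scales == 1)) {
    abort("`scales` must be nonempty and include 1.0")
  }
  check_number(max_translation, "max_translation", min = 0)
  check_number(min_overlap_fraction, "min_overlap_fraction", min = 0, max = 1)
  check_number(max_intensity, "max_intensity", min = 1)
  structure(list(parts_rows = as.integer(parts_rows),
                 parts_cols = as.integer(parts_cols),
                 scales = as.numeric(scales),
                 max_translation = as.integer(max_translation),
                 min_overlap_fraction = min_overlap_fraction,
                 max_intensity = max_intensity,
                 per_part = isTRUE(per_part)),
            class = "sad_config")
}

#' Part-wise sum-of-absolute-differences similarity
#'
#' Computes the pixel-based similarity between two equally sized
#' (downscaled) patterns: each part of `a` is matched against candidate
#' regions of `b` over the configured scale/translation grid (nearest-
#' neighbour sampling on the scaled lattice, with integer translations
#' applied in the part's scaled coordinate frame); the candidate
#' similarity is `1 - SAD / (overlap * max_intensity)` over the in-bounds
#' overlap, and the final score is the mean over parts of the per-part
#' maxima (or the global maximum of the part mean when
#' `cfg$per_part = FALSE`). Higher is more similar; the self-score is
#' exactly 1. Scores are asymmetric in principle (parts of `a` are searched
#' in `b`); store and rank them in the query direction.
#'
#' @param a,b Numeric matrices of identical dimensions (use
#'   [downscale_quarter()] first, as the matcher is designed for quarter
#'   resolution).
#' @param cfg A [sad_config()].
#' @return A similarity score in `[0, 1]`, with attribute `part_scores`.
#' @examples
#' p <- matrix(runif(64, 0, 255), 8, 8)
#' sad_similarity(p, p, sad_config(parts_rows = 1, parts_cols = 1))
#' @export
sad_similarity <- function(a, b, cfg = sad_config()) {
  stopifnot(inherits(cfg, "sad_config"))
  a <- to_gray(a); b <- to_gray(b)
  if (!all(dim(a) == dim(b))) abort("`a` and `b` must have identical dimensions")
  res <- sad_similarity_cpp(a, b, cfg$parts_rows, cfg$parts_cols,
                            cfg$scales, cfg$max_translation,
                            cfg$min_overlap_fraction, cfg$max_intensity,
                            cfg$per_part)
  structure(res$score, part_scores = res$part_scores)
}

#' Configuration for the patch-grid template matcher
#'
#' The template matcher (ITM style) splits the full-resolution pattern into
#' an equal patch grid (e.g. 2x7 for elongate strips, 3x2 for compact
#' bellies), slides each patch over the other image within a margin of its
#' home position, and scores each patch by its maximum zero-mean normalized
#' cross-correlation. No downscaling and no scale search are performed.
#'
#' @param patch_rows,patch_cols Patch grid (remainder to the last row/col).
#' @param mode `"binary"` (inputs must be binarized) or `"color"` (channels
#'   scored separately and averaged).
#' @param slide_margin Maximum slide in pixels around the home position.
#' @param constant_patch_score Score assigned to zero-variance patches.
#' @return An `itm_config` object.
#' @export
itm_config <- function(patch_rows = 2, patch_cols = 7,
                       mode = c("binary", "color"), slide_margin = 20,
                       constant_patch_score = 0) {
  mode <- match.arg(mode)
  check_number(patch_rows, "patch_rows", min = 1)
  check_number(patch_cols, "patch_cols", min = 1)
  check_number(slide_margin, "slide_margin", min = 0)
  check_number(constant_patch_score, "constant_patch_score")
  structure(list(patch_rows = as.integer(patch_rows),
                 patch_cols = as.integer(patch_cols), mode = mode,
                 slide_margin = as.integer(slide_margin),
                 constant_patch_score = constant_patch_score),
            class = "itm_config")
}

#' Patch-grid normalized cross-correlation similarity
#'
#' Slides each patch of `a` over `b` within `cfg$slide_margin` of its home
#' position and takes the maximum normalized correlation coefficient; the
#' total score is the sum over patches, so a self-match with non-constant
#' patches scores exactly `patch_rows * patch_cols`. In `"color"` mode the
#' per-channel correlations are averaged per patch.
#'
#' @param a,b Patterns of identical dimensions (matrices, or 3-d arrays in
#'   color mode). Binary mode requires two-valued inputs (see [binarize()]).
#' @param cfg An [itm_config()].
#' @return Total score in `[-patch_count, patch_count]`, with attributes
#'   `patch_scores` and `best_offsets` (per-patch argmax `(dr, dc)`).
#' @export
itm_similarity <- function(a, b, cfg = itm_config()) {
  stopifnot(inherits(cfg, "itm_config"))
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || !all(da == db)) {
    abort("`a` and `b` must have identical dimensions")
  }
  if (cfg$mode == "binary") {
    if (!is_binary_pattern(a) || !is_binary_pattern(b)) {
      abort("binary mode requires binarized (two-valued) inputs")
    }
  }
  channels <- if (length(da) == 3L) seq_len(da[3]) else 0L
  acc <- NULL
  for (ch in channels) {
    am <- if (ch == 0L) to_gray(a) else to_gray(a[, , ch])
    bm <- if (ch == 0L) to_gray(b) else to_gray(b[, , ch])
    res <- itm_similarity_cpp(am, bm, cfg$patch_rows, cfg$patch_cols,
                              cfg$slide_margin, cfg$constant_patch_score)
    if (is.null(acc)) {
      acc <- res
      acc$n <- 1L
    } else {
      acc$patch_scores <- acc$patch_scores + res$patch_scores
      acc$n <- acc$n + 1L
    }
  }
  patch_scores <- acc$patch_scores / acc$n
  structure(sum(patch_scores),
            patch_scores = patch_scores,
            best_offsets = cbind(dr = acc$best_dr, dc = acc$best_dc))
}
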