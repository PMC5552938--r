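#' Straighten a curved body axis along a spine polyline
#'
#' Resamples the image in arc-length/normal coordinates of the spine: output
#' row `t` (1-based) is sampled along the unit normal of the spine at arc
#' length `t - 1`, centered on the spine, with bilinear interpolation.
#' Out-of-bounds samples are filled with the median border intensity (or
#' `fill`). The output has `round(arc length)` rows and `out_width` columns,
#' so a straight vertical spine reproduces the centered crop of the input.
#'
#' @param image Intensity matrix (or RGB array, converted by luma weights).
#' @param spine Two-column matrix or data frame of `(row, col)` vertices,
#'   1-based image coordinates, at least two distinct vertices.
#' @param out_width Output width in pixels.
#' @param fill Background fill; defaults to the median border intensity.
#' @return Numeric matrix `round(arc length) x out_width`.
#' @export
straighten <- function(image, spine, out_width, fill = NULL) {
  img <- to_gray(image)
  sp <- as.matrix(spine)
  if (ncol(sp) != 2 || nrow(sp) < 2) {
    abort("`spine` must be a (row, col) polyline with >= 2 vertices")
  }
  storage.mode(sp) <- "double"
  seg <- diff(sp)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen <= 0)) abort("spine arc length must be strictly increasing")
  L <- sum(seglen)
  if (L < 2) abort("spine shorter than 2 px")
  H_out <- as.integer(round(L))
  W_out <- as.integer(out_width)

  cum <- c(0, cumsum(seglen))
  s_t <- 0:(H_out - 1L)
  k <- findInterval(s_t, cum, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), nrow(sp) - 1L)
  frac <- (s_t - cum[k]) / seglen[k]
  p_r <- sp[k, 1] + frac * seg[k, 1]
  p_c <- sp[k, 2] + frac * seg[k, 2]
  t_r <- seg[k, 1] / seglen[k]
  t_c <- seg[k, 2] / seglen[k]
  n_r <- -t_c
  n_c <- t_r

  # flag normals that cross within the sampled band (sharp bends)
  if (H_out > 1) {
    dth <- abs(diff(atan2(t_c, t_r)))
    dth <- pmin(dth, 2 * pi - dth)
    if (any(dth * (W_out / 2) > 1.5)) {
      warn("spine curvature is high relative to `out_width`; adjacent normals may self-intersect")
    }
  }

  u <- (0:(W_out - 1L)) - (W_out - 1) / 2
  rr <- outer(p_r, rep(1, W_out)) + outer(n_r, u)
  cc <- outer(p_c, rep(1, W_out)) + outer(n_c, u)
  if (is.null(fill)) {
    fill <- median(c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)]))
  }
  vals <- bilinear_sample_cpp(img, as.vector(rr), as.vector(cc), fill)
  matrix(vals, H_out, W_out)
}

#' Crop a rectangular pattern region
#'
#' Exact sub-grid copy of the `height x width` rectangle with top-left corner
#' at `(top, left)` (1-based, inclusive). The rectangle must lie within the
#' image.
#'
#' @param image Intensity matrix or array.
#' @param top,left 1-based corner position.
#' @param height,width Rectangle size in pixels.
#' @return Matrix of dimensions `(height, width)` (channels preserved for
#'   arrays).
#' @export
crop_image <- function(image, top, left, height, width) {
  d <- dim(image)
  check_number(top, "top", min = 1)
  check_number(left, "left", min = 1)
  check_number(height, "height", min = 1)
  check_number(width, "width", min = 1)
  if (top + height - 1 > d[1] || left + width - 1 > d[2]) {
    abort("crop rectangle exceeds image bounds")
  }
  rows <- top:(top + height - 1)
  cols <- left:(left + width - 1)
  if (length(d) == 3L) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}

#' Binarize a pattern by thresholding
#'
#' Computes a global threshold (Otsu's between-class-variance criterion, via
#' \pkg{EBImage}, or a fixed value) and assigns foreground to the
#' polarity-selected side: `dark_fg` takes pixels strictly below the
#' threshold, `light_fg` pixels at or above it. The output is two-valued with
#' the foreground drawn at its polarity-consistent intensity (0 for
#' `dark_fg`, 255 for `light_fg`), which makes the operation idempotent on
#' its own output.
#'
#' @param image Intensity matrix (RGB arrays are converted by luma weights
#'   0.299/0.587/0.114 first).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required for `method = "fixed"`.
#' @param polarity `"dark_fg"` or `"light_fg"`.
#' @return Integer matrix with values `{0, 255}`; attributes `foreground`
#'   (the foreground intensity) and `threshold`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("dark_fg", "light_fg")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  img <- to_gray(image)
  if (method == "otsu") {
    if (diff(range(img)) == 0) {
      abort("no threshold separates classes: image is constant")
    }
    threshold <- EBImage::otsu(img, range = c(0, 255), levels = 256L)
  } else {
    if (is.null(threshold)) abort("`threshold` is required for method = \"fixed\"")
    check_number(threshold, "threshold")
  }
  fg_mask <- if (polarity == "dark_fg") img < threshold else img >= threshold
  fg <- if (polarity == "dark_fg") 0L else 255L
  bg <- 255L - fg
  out <- matrix(bg, nrow(img), ncol(img))
  out[fg_mask] <- fg
  out <- as_intensity(out, foreground = fg)
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Downscale by 25% per dimension with 4x4 block averaging
#'
#' Each output pixel is the arithmetic mean of its 4x4 source block, so a
#' `320 x 1280` pattern becomes `80 x 320`. Dimensions not divisible by 4 are
#' first padded by edge replication. Means are kept in floating point;
#' rounding to 8-bit happens only on image export.
#'
#' @param image Intensity matrix (RGB arrays converted to gray first).
#' @return Numeric matrix of a quarter the size per dimension.
#' @export
downscale_quarter <- function(image) {
  m <- to_gray(image)
  H <- nrow(m); W <- ncol(m)
  padr <- (4 - H %% 4) %% 4
  padc <- (4 - W %% 4) %% 4
  if (padr > 0) m <- m[c(seq_len(H), rep(H, padr)), , drop = FALSE]
  if (padc > 0) m <- m[, c(seq_len(W), rep(W, padc)), drop = FALSE]
  H <- nrow(m); W <- ncol(m)
  # average row blocks, then column blocks (column-major reshape)
  r1 <- colMeans(array(m, c(4L, H %/% 4L, W)), dims = 1)
  r2 <- colMeans(array(t(r1), c(4L, W %/% 4L, H %/% 4L)), dims = 1)
  out <- t(r2)
  fgattr <- attr(image, "foreground")
  if (!is.null(fgattr)) attr(out, "foreground") <- fgattr
  out
}
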