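#' Detect keypoints (and optionally descriptors) in a pattern
#'
#' Two pluggable detectors are provided. `blob_binary` operates on a binary
#' pattern and returns the centroid and area-derived scale
#' (`sqrt(area / pi)`) of every foreground connected component — the
#' location-only representation used by the point-affine matcher.
#' `si_descriptor` additionally extracts, for each blob of the intensity
#' image (located on an internally Otsu-binarized copy), a scale-adapted
#' square intensity patch resampled to `descriptor_size^2` pixels and
#' normalized to zero mean / unit norm — a lightweight local descriptor in
#' the spirit of scale-invariant features, not a SIFT/SURF reimplementation.
#' Both detectors are deterministic.
#'
#' @param pattern Intensity or binary matrix. `blob_binary` requires a
#'   two-valued input; the foreground value is taken from the `foreground`
#'   attribute (as set by [binarize()]) or the minority pixel class.
#' @param detector `"blob_binary"` or `"si_descriptor"`.
#' @param min_area Components smaller than this many pixels are ignored.
#' @param descriptor_size Side length of the resampled descriptor patch.
#' @return A `feature_set`: list with `keypoints` (tibble `row`, `col`,
#'   `scale`), `descriptors` (matrix or `NULL`), and the source image
#'   dimensions `dim`.
#' @export
detect_features <- function(pattern,
                            detector = c("blob_binary", "si_descriptor"),
                            min_area = 4, descriptor_size = 8) {
  detector <- match.arg(detector)
  if (length(pattern) == 0L) abort("`pattern` must be nonempty")
  img <- to_gray(pattern)

  if (detector == "blob_binary") {
    if (!is_binary_pattern(img)) {
      abort("blob_binary requires a binary (two-valued) pattern")
    }
    fg <- attr(pattern, "foreground")
    if (is.null(fg)) {
      vals <- sort(unique(as.vector(img)))
      fg <- if (length(vals) == 1L) vals else {
        if (sum(img == vals[1]) <= sum(img == vals[2])) vals[1] else vals[2]
      }
    }
    mask <- img == fg
    kp <- blob_centroids(mask, min_area)
    return(new_feature_set(kp, NULL, dim(img)))
  }

  # si_descriptor: keypoints from blobs of the binarized image, descriptors
  # sampled from the intensity image
  if (diff(range(img)) == 0) {
    return(new_feature_set(tibble(row = double(), col = double(),
                                  scale = double()), NULL, dim(img)))
  }
  bin <- binarize(img, method = "otsu", polarity = "dark_fg")
  mask <- bin == attr(bin, "foreground")
  if (sum(mask) > length(mask) / 2) mask <- !mask  # descriptor anchors on the minority class
  kp <- blob_centroids(mask, min_area)
  if (nrow(kp) == 0L) return(new_feature_set(kp, NULL, dim(img)))
  k <- descriptor_size
  desc <- matrix(0, nrow(kp), k * k)
  for (i in seq_len(nrow(kp))) {
    half <- max(4, 2.5 * kp$scale[i])
    gr <- seq(kp$row[i] - half, kp$row[i] + half, length.out = k)
    gc <- seq(kp$col[i] - half, kp$col[i] + half, length.out = k)
    v <- bilinear_sample_cpp(img, rep(gr, times = k), rep(gc, each = k),
                             fill = median(img))
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    desc[i, ] <- v
  }
  new_feature_set(kp, desc, dim(img))
}

blob_centroids <- function(mask, min_area) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab == 0L) return(tibble(row = double(), col = double(), scale = double()))
  px <- which(lab > 0)
  l <- lab[px]
  H <- nrow(mask)
  ri <- (px - 1L) %% H + 1L
  ci <- (px - 1L) %/% H + 1L
  area <- tabulate(l, nlab)
  keep <- which(area >= min_area)
  if (length(keep) == 0L) {
    return(tibble(row = double(), col = double(), scale = double()))
  }
  rows <- vapply(keep, function(lb) mean(ri[l == lb]), numeric(1))
  cols <- vapply(keep, function(lb) mean(ci[l == lb]), numeric(1))
  tibble(row = rows, col = cols, scale = sqrt(area[keep] / pi))
}

new_feature_set <- function(keypoints, descriptors, dim) {
  if (!is.null(descriptors) && nrow(descriptors) != nrow(keypoints)) {
    abort("descriptor count must match keypoint count")
  }
  structure(list(keypoints = keypoints, descriptors = descriptors,
                 dim = as.integer(dim)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d keypoints%s (source %dx%d)\n",
              nrow(x$keypoints),
              if (is.null(x$descriptors)) "" else
                sprintf(", %d-d descriptors", ncol(x$descriptors)),
              x$dim[1], x$dim[2]))
  invisible(x)
}

#' @export
tidy.feature_set <- function(x, ...) x$keypoints

#' Configuration for descriptor matching with geometric verification
#'
#' @param ratio_threshold Nearest/second-nearest descriptor distance ratio
#'   below which a correspondence is kept (Lowe-style ratio test).
#' @param model Geometric model fitted to correspondence locations:
#'   `"similarity"` (translation + rotation + scale) or `"affine"`.
#' @param inlier_tolerance Inlier radius as a fraction of the image diagonal.
#' @param min_correspondences Fewer ratio-test correspondences than this
#'   score 0.
#' @param ransac_iterations,ransac_seed Random-sampling consensus control.
#' @return A `geo_match_config` object.
#' @export
geo_match_config <- function(ratio_threshold = 0.8,
                             model = c("similarity", "affine"),
                             inlier_tolerance = 0.02,
                             min_correspondences = 3,
                             ransac_iterations = 500, ransac_seed = 42) {
  model <- match.arg(model)
  check_number(ratio_threshold, "ratio_threshold", min = 1e-9, max = 1 - 1e-9)
  check_number(inlier_tolerance, "inlier_tolerance", min = 0)
  check_number(min_correspondences, "min_correspondences", min = 3)
  check_number(ransac_iterations, "ransac_iterations", min = 1)
  structure(list(ratio_threshold = ratio_threshold, model = model,
                 inlier_tolerance = inlier_tolerance,
                 min_correspondences = as.integer(min_correspondences),
                 ransac_iterations = as.integer(ransac_iterations),
                 ransac_seed = as.integer(ransac_seed)),
            class = "geo_match_config")
}

#' Descriptor-matching score with geometric verification
#'
#' Candidate correspondences are found by nearest-neighbour descriptor
#' matching filtered by the ratio test; a robust geometric model
#' (seeded random-sampling consensus, ties broken by lower mean inlier
#' residual, followed by a least-squares refit on the inliers) is fitted to
#' the correspondence locations; the score is the number of inliers within
#' `inlier_tolerance` of the model. This "goodness of fit" count is a
#' surrogate for unpublished commercial scores, not a clone of any of them.
#'
#' @param fa,fb `feature_set` objects carrying descriptors.
#' @param cfg A [geo_match_config()].
#' @return Inlier count (>= 0), with attributes `n_correspondences` and
#'   `inlier_fraction`.
#' @export
geometric_match_score <- function(fa, fb, cfg = geo_match_config()) {
  stopifnot(inherits(fa, "feature_set"), inherits(fb, "feature_set"))
  if (is.null(fa$descriptors) || is.null(fb$descriptors)) {
    abort("geometric matching requires descriptors in both feature sets")
  }
  na <- nrow(fa$keypoints); nb <- nrow(fb$keypoints)
  if (na < cfg$min_correspondences || nb < 2) {
    return(structure(0, n_correspondences = 0L, inlier_fraction = NA_real_))
  }
  # cross descriptor distances
  d2 <- outer(rowSums(fa$descriptors^2), rowSums(fb$descriptors^2), "+") -
    2 * fa$descriptors %*% t(fb$descriptors)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  corr_a <- integer(0); corr_b <- integer(0)
  for (i in seq_len(na)) {
    o <- order(dmat[i, ])[1:2]
    d1 <- dmat[i, o[1]]; d2n <- dmat[i, o[2]]
    ok <- if (d2n == 0) d1 == 0 else (d1 / d2n) <= cfg$ratio_threshold
    if (ok) {
      corr_a <- c(corr_a, i); corr_b <- c(corr_b, o[1])
    }
  }
  ncorr <- length(corr_a)
  if (ncorr < cfg$min_correspondences) {
    return(structure(0, n_correspondences = ncorr, inlier_fraction = NA_real_))
  }
  A <- as.matrix(fa$keypoints[corr_a, c("row", "col")])
  B <- as.matrix(fb$keypoints[corr_b, c("row", "col")])
  diag_len <- sqrt(sum(fa$dim^2))
  tol <- cfg$inlier_tolerance * diag_len
  msize <- if (cfg$model == "similarity") 2L else 3L

  fit_exact <- function(idx) fit_model(A[idx, , drop = FALSE],
                                       B[idx, , drop = FALSE], cfg$model)
  resids <- function(mod) {
    TA <- A %*% t(mod$M) + matrix(mod$t, ncorr, 2, byrow = TRUE)
    sqrt(rowSums((TA - B)^2))
  }

  withr::local_seed(cfg$ransac_seed)
  best <- list(count = -1L, meanres = Inf, inl = NULL)
  for (it in seq_len(cfg$ransac_iterations)) {
    idx <- sample.int(ncorr, msize)
    mod <- fit_exact(idx)
    if (is.null(mod)) next
    r <- resids(mod)
    inl <- r <= tol
    cnt <- sum(inl)
    mres <- if (cnt > 0) mean(r[inl]) else Inf
    if (cnt > best$count || (cnt == best$count && mres < best$meanres)) {
      best <- list(count = cnt, meanres = mres, inl = inl)
    }
  }
  if (best$count >= msize) {
    # least-squares refit on the inliers, keep if it does not lose inliers
    mod <- fit_model(A[best$inl, , drop = FALSE], B[best$inl, , drop = FALSE],
                     cfg$model, ls = TRUE)
    if (!is.null(mod)) {
      r <- resids(mod)
      inl <- r <= tol
      cnt <- sum(inl)
      mres <- if (cnt > 0) mean(r[inl]) else Inf
      if (cnt > best$count || (cnt == best$count && mres < best$meanres)) {
        best <- list(count = cnt, meanres = mres, inl = inl)
      }
    }
  }
  score <- max(best$count, 0L)
  if (score < cfg$min_correspondences) score <- 0L
  structure(as.numeric(score), n_correspondences = ncorr,
            inlier_fraction = score / ncorr)
}

# exact or least-squares fit of a 2-d similarity/affine map A -> B;
# returns list(M = 2x2, t = length-2) or NULL when degenerate
fit_model <- function(A, B, model, ls = FALSE) {
  n <- nrow(A)
  if (model == "similarity") {
    za <- complex(real = A[, 1], imaginary = A[, 2])
    zb <- complex(real = B[, 1], imaginary = B[, 2])
    ma <- mean(za); mb <- mean(zb)
    va <- sum(Mod(za - ma)^2)
    if (va < 1e-12) return(NULL)
    w <- sum(Conj(za - ma) * (zb - mb)) / va
    M <- matrix(c(Re(w), Im(w), -Im(w), Re(w)), 2, 2)
    t <- c(Re(mb), Im(mb)) - M %*% c(Re(ma), Im(ma))
    return(list(M = M, t = as.numeric(t)))
  }
  X <- cbind(A, 1)
  fit <- tryCatch(qr.solve(qr(X, LAPACK = TRUE), B), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit) || any(!is.finite(fit))) return(NULL)
  if (!ls && abs(det(cbind(A[2, ] - A[1, ], A[3, ] - A[1, ]))) < 1e-9) {
    return(NULL)
  }
  list(M = t(fit[1:2, ]), t = as.numeric(fit[3, ]))
}

#' Configuration for keypoint-location-only affine matching
#'
#' @param model Transform model; only `"affine"` is implemented.
#' @param residual_scale Residual (pixels) at which the score halves.
#' @param min_points Minimum keypoints per set (>= 3).
#' @param ransac_iterations,ransac_seed Random triple-sampling control.
#' @return A `point_match_config` object.
#' @export
point_match_config <- function(model = "affine", residual_scale = 5,
                               min_points = 3, ransac_iterations = 1500,
                               ransac_seed = 42) {
  model <- match.arg(model, "affine")
  check_number(residual_scale, "residual_scale", min = 1e-9)
  check_number(min_points, "min_points", min = 3)
  check_number(ransac_iterations, "ransac_iterations", min = 1)
  structure(list(model = model, residual_scale = residual_scale,
                 min_points = as.integer(min_points),
                 ransac_iterations = as.integer(ransac_iterations),
                 ransac_seed = as.integer(ransac_seed)),
            class = "point_match_config")
}

#' Keypoint-location-only affine matching score
#'
#' Estimates a robust affine transform between two keypoint sets using only
#' their locations (descriptors are ignored): random triples of points from
#' each set propose exact affine maps (degenerate and strongly
#' area-distorting maps are rejected), each map is scored by the mean
#' nearest-neighbour distance from the transformed `fa` points to `fb`, and
#' the best map is polished by trimmed iterative-closest-point refinement.
#' The score is `1 / (1 + residual / residual_scale)`, in `(0, 1]`; identical
#' sets score 1. The reciprocal-residual form is a documented stand-in for
#' unpublished commercial score formulas.
#'
#' @param fa,fb `feature_set` objects (locations used, descriptors ignored).
#' @param cfg A [point_match_config()].
#' @return Score in `(0, 1]`, with attribute `residual` (pixels).
#' @export
point_affine_score <- function(fa, fb, cfg = point_match_config()) {
  stopifnot(inherits(fa, "feature_set"), inherits(fb, "feature_set"))
  na <- nrow(fa$keypoints); nb <- nrow(fb$keypoints)
  if (na < cfg$min_points || nb < cfg$min_points) {
    abort("insufficient keypoints for point-affine matching")
  }
  A <- as.matrix(fa$keypoints[, c("row", "col")])
  B <- as.matrix(fb$keypoints[, c("row", "col")])
  withr::local_seed(cfg$ransac_seed)
  iters <- cfg$ransac_iterations
  # triples drawn with replacement; duplicated indices yield singular
  # 3-point systems and are discarded inside the solver
  idxA <- matrix(sample.int(na, 3L * iters, replace = TRUE), iters, 3L) - 1L
  idxB <- matrix(sample.int(nb, 3L * iters, replace = TRUE), iters, 3L) - 1L
  res <- point_affine_cpp(A, B, idxA, idxB, refine_iters = 10L,
                          det_min = 0.25, det_max = 4)
  structure(1 / (1 + res$residual / cfg$residual_scale),
            residual = res$residual, transform = res$M, offset = res$t)
}
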