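make_circle_pattern <- function(centers, radius = 5, H = 60, W = 80) {
  m <- matrix(255L, H, W)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if ((r - centers[i, 1])^2 + (c - centers[i, 2])^2 <= radius^2) {
        m[r, c] <- 0L
      }
    }
  }
  attr(m, "foreground") <- 0L
  m
}

test_that("blob_binary finds circle centroids to sub-pixel accuracy", {
  centers <- rbind(c(15, 20), c(40, 60), c(20, 70))
  img <- make_circle_pattern(centers)
  fs <- detect_features(img, "blob_binary")
  expect_equal(nrow(fs$keypoints), 3)
  kp <- as.matrix(fs$keypoints[order(fs$keypoints$row), c("row", "col")])
  ctr <- centers[order(centers[, 1]), ]
  expect_true(all(abs(kp - ctr) <= 0.5))
  expect_true(all(abs(fs$keypoints$scale - 5) < 1))
})

test_that("feature detection is deterministic and scales with the image", {
  img <- make_circle_pattern(rbind(c(15, 20), c(40, 60), c(20, 70)))
  expect_identical(detect_features(img, "blob_binary"),
                   detect_features(img, "blob_binary"))
  # 2x nearest-neighbour upscale doubles the centroids within a pixel
  up <- img[rep(seq_len(nrow(img)), each = 2), rep(seq_len(ncol(img)), each = 2)]
  attr(up, "foreground") <- 0L
  f1 <- detect_features(img, "blob_binary")
  f2 <- detect_features(up, "blob_binary")
  o1 <- order(f1$keypoints$row); o2 <- order(f2$keypoints$row)
  expect_true(all(abs(2 * f1$keypoints$row[o1] - f2$keypoints$row[o2]) <= 1.1))
  expect_true(all(abs(2 * f1$keypoints$col[o1] - f2$keypoints$col[o2]) <= 1.1))
})

test_that("blob_binary rejects non-binary input; empty patterns give empty sets", {
  expect_error(detect_features(matrix(runif(100), 10, 10), "blob_binary"),
               "binary")
  blank <- matrix(255L, 10, 10)
  attr(blank, "foreground") <- 0L
  fs <- detect_features(blank, "blob_binary")
  expect_equal(nrow(fs$keypoints), 0)
})

test_that("si_descriptor emits aligned descriptors deterministically", {
  db <- generate_database(1, 2, small_spec(), small_params(), seed = 3)
  p <- db$captures$pattern[[1]]
  f1 <- detect_features(p, "si_descriptor")
  f2 <- detect_features(p, "si_descriptor")
  expect_identical(f1, f2)
  expect_equal(nrow(f1$descriptors), nrow(f1$keypoints))
  expect_gt(nrow(f1$keypoints), 2)
})

test_that("geometric matching scores identical sets at the full feature count", {
  db <- generate_database(1, 1, small_spec(), capture_params(), seed = 5)
  f <- detect_features(db$captures$pattern[[1]], "si_descriptor")
  n <- nrow(f$keypoints)
  expect_gte(n, 3)
  expect_equal(as.numeric(geometric_match_score(f, f)), n)
})

test_that("geometric matching recovers sets moved by a fixed affine map", {
  db <- generate_database(1, 1, small_spec(), capture_params(), seed = 6)
  f <- detect_features(db$captures$pattern[[1]], "si_descriptor")
  n <- nrow(f$keypoints)
  M <- matrix(c(1.05, 0.02, -0.03, 0.97), 2, 2)
  moved <- f
  xy <- as.matrix(f$keypoints[, c("row", "col")]) %*% t(M)
  moved$keypoints$row <- xy[, 1] + 3
  moved$keypoints$col <- xy[, 2] - 2
  cfg <- geo_match_config(model = "affine")
  expect_equal(as.numeric(geometric_match_score(f, moved, cfg)), n)
})

test_that("too-few keypoints or missing descriptors are handled as specified", {
  kp <- tibble::tibble(row = c(1, 5), col = c(2, 8), scale = c(1, 1))
  f2 <- structure(list(keypoints = kp,
                       descriptors = matrix(runif(8), 2, 4),
                       dim = c(20L, 20L)), class = "feature_set")
  expect_equal(as.numeric(geometric_match_score(f2, f2)), 0)
  f_nodesc <- structure(list(keypoints = kp, descriptors = NULL,
                             dim = c(20L, 20L)), class = "feature_set")
  expect_error(geometric_match_score(f_nodesc, f_nodesc), "descriptors")
  expect_error(point_affine_score(f_nodesc, f_nodesc), "insufficient keypoints")
})

test_that("point-affine matching scores identical and affinely moved sets near 1", {
  img <- make_circle_pattern(rbind(c(10, 12), c(30, 40), c(45, 20), c(20, 66),
                                   c(50, 60)), radius = 4)
  f <- detect_features(img, "blob_binary")
  s_self <- point_affine_score(f, f)
  expect_equal(as.numeric(s_self), 1)
  expect_lt(attr(s_self, "residual"), 1e-9)

  M <- matrix(c(0.96, -0.05, 0.04, 1.06), 2, 2)
  moved <- f
  xy <- as.matrix(f$keypoints[, c("row", "col")]) %*% t(M)
  moved$keypoints$row <- xy[, 1] + 4
  moved$keypoints$col <- xy[, 2] + 1
  s <- point_affine_score(f, moved)
  expect_lt(attr(s, "residual"), 1e-6)
  expect_gt(as.numeric(s), 0.999)
})

test_that("point-affine score is invariant under a shared rigid motion", {
  withr::local_seed(8)
  A <- cbind(runif(9, 10, 50), runif(9, 10, 70))
  B <- A + matrix(rnorm(18, 0, 1.5), ncol = 2)   # noisy counterpart
  fs <- function(m) structure(list(
    keypoints = tibble::tibble(row = m[, 1], col = m[, 2], scale = 2),
    descriptors = NULL, dim = c(60L, 80L)), class = "feature_set")
  s0 <- point_affine_score(fs(A), fs(B))
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(7, -3)
  rot <- function(m) sweep(m %*% t(R), 2, -shift)
  s1 <- point_affine_score(fs(rot(A)), fs(rot(B)))
  expect_equal(as.numeric(s0), as.numeric(s1), tolerance = 1e-6)
})

test_that("unstable spots hurt the location-only matcher more than pixel SAD", {
  # crowded elongated spots whose 1-px erosion/dilation merges or splits
  # components: the pixel matcher shrugs this off, keypoint locations do not
  spec <- pattern_spec(64, 256, 25, 35, 6, 10, spot_shape = "elongated")
  params <- capture_params(spot_morph_prob = 0.9)
  db <- generate_database(20, 2, spec, params, seed = 21)
  tab_sad <- all_pairs_scores(db, matcher_sad())
  tab_pa <- suppressWarnings(all_pairs_scores(db, matcher_feature_points()))
  top_sad <- mean(match_ranks(db, tab_sad, 1)$rank == 1)
  top_pa <- mean(match_ranks(db, tab_pa, 1)$rank == 1)
  expect_gt(top_sad, top_pa)
})
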