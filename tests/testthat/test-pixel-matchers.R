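test_that("SAD self-similarity is exactly 1 and complements score 0", {
  set.seed(1)
  p <- matrix(runif(40 * 90, 0, 255), 40, 90)
  expect_identical(as.numeric(sad_similarity(p, p)), 1)
  expect_identical(as.numeric(sad_similarity(p, p, sad_config(3, 4, per_part = FALSE))), 1)
  b <- matrix(0, 12, 12); b[3:7, 4:9] <- 255
  cfg1 <- sad_config(1, 1, scales = 1, max_translation = 0)
  expect_identical(as.numeric(sad_similarity(b, 255 - b, cfg1)), 0)
})

test_that("SAD matches the exhaustive oracle on random small instances", {
  set.seed(2)
  for (i in 1:25) {
    H <- sample(6:14, 1); W <- sample(6:14, 1)
    a <- matrix(runif(H * W, 0, 255), H, W)
    b <- matrix(runif(H * W, 0, 255), H, W)
    pr <- sample(1:2, 1); pc <- sample(1:2, 1)
    sc <- sort(sample(c(0.9, 0.95, 1.05, 1.1), sample(0:2, 1)))
    sc <- c(1, sc)
    tmax <- sample(0:2, 1)
    ov <- runif(1, 0.2, 0.8)
    per_part <- i %% 4 != 0
    got <- as.numeric(sad_similarity(a, b, sad_config(pr, pc, sc, tmax, ov,
                                                      per_part = per_part)))
    want <- sad_oracle(a, b, pr, pc, sc, tmax, ov, per_part = per_part)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("enlarging the SAD transform grid never decreases the score", {
  set.seed(3)
  for (i in 1:10) {
    a <- matrix(runif(144, 0, 255), 12, 12)
    b <- matrix(runif(144, 0, 255), 12, 12)
    s_small <- sad_similarity(a, b, sad_config(2, 2, scales = 1,
                                               max_translation = 1))
    s_big <- sad_similarity(a, b, sad_config(2, 2, scales = c(0.9, 1, 1.1),
                                             max_translation = 3))
    expect_gte(as.numeric(s_big) + 1e-12, as.numeric(s_small))
  }
})

test_that("SAD part tiling assigns remainders to the last row/column", {
  p <- matrix(runif(100, 0, 255), 10, 10)
  s <- sad_similarity(p, p, sad_config(3, 3, scales = 1, max_translation = 0))
  expect_length(attr(s, "part_scores"), 9)
  expect_equal(as.numeric(s), 1)
})

test_that("SAD config validation enforces the documented invariants", {
  expect_error(sad_config(scales = c(0.9, 1.1)), "include 1.0")
  expect_error(sad_config(min_overlap_fraction = 1.5), "min_overlap_fraction")
  expect_error(sad_similarity(matrix(0, 4, 4), matrix(0, 5, 5)),
               "identical dimensions")
})

test_that("ITM self-match scores exactly the patch count", {
  set.seed(4)
  p <- matrix(runif(60 * 140, 0, 255), 60, 140)
  cfg <- itm_config(2, 7, "color", slide_margin = 3)
  s <- itm_similarity(p, p, cfg)
  expect_equal(as.numeric(s), 14, tolerance = 1e-12)
  off <- attr(s, "best_offsets")
  expect_true(all(off == 0))
})

test_that("ITM matches the correlation oracle on random small instances", {
  set.seed(5)
  for (i in 1:25) {
    H <- sample(8:16, 1); W <- sample(8:16, 1)
    a <- matrix(runif(H * W, 0, 255), H, W)
    b <- matrix(runif(H * W, 0, 255), H, W)
    pr <- sample(1:2, 1); pc <- sample(1:2, 1)
    m <- sample(0:2, 1)
    got <- as.numeric(itm_similarity(a, b, itm_config(pr, pc, "color", m)))
    want <- itm_oracle(a, b, pr, pc, m)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a translated copy realigns at the translation offset", {
  set.seed(6)
  d <- 2
  a <- matrix(runif(40 * 60, 0, 255), 40, 60)
  b <- matrix(median(a), 40, 60)
  b[(1 + d):40, (1 + d):60] <- a[1:(40 - d), 1:(60 - d)]
  # b holds a shifted by (+d, +d): interior patches re-find themselves at
  # (d, d) with perfect correlation (border patches clip at the image edge)
  s <- itm_similarity(a, b, itm_config(3, 3, "color", slide_margin = 4))
  off <- attr(s, "best_offsets")
  center <- 5L  # row-major patch index of the interior patch
  expect_equal(unname(off[center, ]), c(d, d))
  expect_equal(attr(s, "patch_scores")[center], 1, tolerance = 1e-12)
})

test_that("constant patches score the configured constant value", {
  a <- matrix(0, 20, 20); a[1:10, ] <- matrix(runif(200, 0, 255), 10, 20)
  b <- a
  cfg <- itm_config(2, 1, "color", 2, constant_patch_score = -0.5)
  s <- itm_similarity(a, b, cfg)
  ps <- attr(s, "patch_scores")
  expect_equal(ps[2], -0.5)
  expect_equal(ps[1], 1, tolerance = 1e-12)
})

test_that("binary mode demands binarized input and color mode averages channels", {
  a <- matrix(runif(100, 0, 255), 10, 10)
  expect_error(itm_similarity(a, a, itm_config(1, 1, "binary", 1)),
               "binarized")
  bin <- binarize(a, "otsu", polarity = "dark_fg")
  s <- itm_similarity(bin, bin, itm_config(1, 1, "binary", 1))
  expect_equal(as.numeric(s), 1, tolerance = 1e-12)
  arr_a <- array(c(a, 255 - a, a), c(10, 10, 3))
  s3 <- itm_similarity(arr_a, arr_a, itm_config(1, 1, "color", 1))
  expect_equal(as.numeric(s3), 1, tolerance = 1e-12)
})

test_that("strip-geometry patch grids produce 14 patch scores", {
  set.seed(7)
  a <- matrix(runif(300 * 1200, 0, 255), 300, 1200)
  s <- itm_similarity(a, a, itm_config(2, 7, "color", slide_margin = 1))
  expect_length(attr(s, "patch_scores"), 14)
  expect_equal(as.numeric(s), 14, tolerance = 1e-9)
})
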