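test_that("straightening along a vertical spine reproduces the centered crop", {
  set.seed(1)
  img <- matrix(runif(100 * 41, 0, 255), 100, 41)
  spine <- cbind(row = c(11, 90), col = c(21, 21))
  st <- straighten(img, spine, out_width = 21)
  expect_identical(dim(st), c(79L, 21L))       # round(arc length) rows
  expect_equal(max(abs(st - img[11:89, 11:31])), 0)
})

test_that("straighten output height equals the rounded arc length", {
  img <- matrix(0, 60, 60)
  spine1 <- cbind(c(10, 20, 50), c(10, 25, 30))
  L1 <- sqrt(10^2 + 15^2) + sqrt(30^2 + 5^2)
  expect_equal(nrow(suppressWarnings(straighten(img, spine1, 5))), round(L1))
  spine2 <- cbind(c(5, 55), c(5, 55))
  expect_equal(nrow(straighten(img, spine2, 5)), round(50 * sqrt(2)))
})

test_that("straighten recovers a pattern drawn along a sine-curved spine", {
  fx <- make_curved_fixture()
  st <- straighten(fx$image, fx$spine, out_width = fx$band)
  n <- min(nrow(st), nrow(fx$ref))
  got <- st[5:(n - 5), 3:(fx$band - 2)]
  ref <- fx$ref[5:(n - 5), 3:(fx$band - 2)]
  expect_lt(mean(abs(got - ref)), 5)
})

test_that("straighten rejects degenerate spines and flags sharp bends", {
  img <- matrix(0, 30, 30)
  expect_error(straighten(img, cbind(10, 10), 5), "2 vertices")
  expect_error(straighten(img, cbind(c(10, 10.5), c(10, 10)), 5), "shorter than 2 px")
  expect_error(straighten(img, cbind(c(10, 10, 20), c(10, 10, 10)), 5),
               "strictly increasing")
  hairpin <- cbind(c(5, 25, 6), c(15, 15, 16))
  expect_warning(straighten(img, hairpin, 21), "self-intersect")
})

test_that("crop_image copies sub-grids exactly and composes", {
  set.seed(2)
  img <- matrix(sample.int(255, 900, replace = TRUE), 30, 30)
  expect_identical(crop_image(img, 1, 1, 30, 30), img)
  expect_equal(as.vector(crop_image(img, 7, 9, 1, 1)), img[7, 9])
  expect_error(crop_image(img, 20, 20, 15, 5), "exceeds image bounds")
  # composition law on random in-bounds rectangle pairs
  for (i in 1:20) {
    t1 <- sample(1:10, 1); l1 <- sample(1:10, 1)
    h1 <- sample(10:20, 1); w1 <- sample(10:20, 1)
    t2 <- sample(1:3, 1); l2 <- sample(1:3, 1)
    h2 <- sample(1:(h1 - t2), 1); w2 <- sample(1:(w1 - l2), 1)
    a <- crop_image(crop_image(img, t1, l1, h1, w1), t2, l2, h2, w2)
    b <- crop_image(img, t1 + t2 - 1, l1 + l2 - 1, h2, w2)
    expect_identical(a, b)
  }
})

test_that("binarize splits two-valued images on the forced partition", {
  set.seed(3)
  img <- matrix(sample(c(10, 200), 400, replace = TRUE), 20, 20)
  bin <- binarize(img, "otsu", polarity = "dark_fg")
  expect_identical(bin == attr(bin, "foreground"), img == 10)
  expect_identical(attr(bin, "foreground"), 0L)
  bin_l <- binarize(img, "otsu", polarity = "light_fg")
  expect_identical(bin_l == attr(bin_l, "foreground"), img == 200)
})

test_that("fixed-threshold binarization selects exactly the sub-threshold ramp columns", {
  ramp <- matrix(rep(0:255, each = 4), 4, 256)
  bin <- binarize(ramp, "fixed", threshold = 128, polarity = "dark_fg")
  fg_cols <- which(colSums(bin == attr(bin, "foreground")) == 4)
  expect_identical(fg_cols, 1:128)  # values 0..127
})

test_that("binarize errors on constant input and is idempotent on its output", {
  expect_error(binarize(matrix(42, 5, 5), "otsu"), "no threshold separates")
  set.seed(4)
  for (pol in c("dark_fg", "light_fg")) {
    img <- matrix(runif(300, 0, 255), 15, 20)
    b1 <- binarize(img, "otsu", polarity = pol)
    b2 <- binarize(b1, "otsu", polarity = pol)
    expect_identical(unclass(b2)[, ], unclass(b1)[, ])
  }
})

test_that("downscale_quarter averages 4x4 blocks and keeps the stated sizes", {
  big <- matrix(0, 320, 1280)
  expect_identical(dim(downscale_quarter(big)), c(80L, 320L))
  expect_identical(dim(downscale_quarter(matrix(0, 960, 800))), c(240L, 200L))
  expect_equal(downscale_quarter(matrix(7, 8, 8)), matrix(7, 2, 2))
  blk <- matrix(0:15, 4, 4)
  expect_equal(as.vector(downscale_quarter(blk)), 7.5)
})

test_that("downscale_quarter preserves the global mean and pads odd sizes by edge replication", {
  set.seed(5)
  img <- matrix(runif(64 * 32, 0, 255), 64, 32)
  expect_equal(mean(downscale_quarter(img)), mean(img))
  odd <- matrix(runif(10 * 9, 0, 255), 10, 9)
  ds <- downscale_quarter(odd)
  expect_identical(dim(ds), c(3L, 3L))
  # last output pixel averages the edge-replicated block
  padded <- odd[c(1:10, 10, 10), c(1:9, 9, 9, 9)]
  expect_equal(ds[3, 3], mean(padded[9:12, 9:12]))
})

test_that("RGB input is converted with luma weights before preprocessing", {
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 100; arr[, , 2] <- 200; arr[, , 3] <- 50
  expected <- 0.299 * 100 + 0.587 * 200 + 0.114 * 50
  expect_equal(downscale_quarter(arr), matrix(expected, 1, 1))
})
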