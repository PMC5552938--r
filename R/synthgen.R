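#' Specify the geometry of a synthetic spot pattern
#'
#' A pattern spec describes the latent binary marking of one individual:
#' canvas size, number of spots, spot size and shape, and polarity. Two
#' presets mirror the two pattern geometries common in amphibian
#' photo-identification: elongate straightened dorsal/ventral strips
#' (newts, salamanders) and compact toad bellies.
#'
#' @param canvas_height,canvas_width Canvas size in pixels.
#' @param n_spots_min,n_spots_max Range of the number of spots per individual.
#' @param spot_radius_min,spot_radius_max Range of the equivalent spot radius
#'   in pixels (spots are ellipses of matching area).
#' @param spot_shape One of `"round"`, `"elongated"`, `"stripe"`.
#' @param polarity `"dark_on_light"` (dark spots, light background) or
#'   `"light_on_dark"`.
#' @return A `pattern_spec` object (a validated list).
#' @examples
#' spec <- pattern_spec(80, 320, 12, 12, 4, 6, spot_shape = "round")
#' img <- generate_individual(spec, seed = 1)
#' @export
pattern_spec <- function(canvas_height = 320, canvas_width = 1280,
                         n_spots_min = 16, n_spots_max = 30,
                         spot_radius_min = 12, spot_radius_max = 30,
                         spot_shape = c("elongated", "round", "stripe"),
                         polarity = c("dark_on_light", "light_on_dark")) {
  spot_shape <- match.arg(spot_shape)
  polarity <- match.arg(polarity)
  check_number(canvas_height, "canvas_height", min = 1)
  check_number(canvas_width, "canvas_width", min = 1)
  check_number(n_spots_min, "n_spots_min", min = 1)
  check_number(n_spots_max, "n_spots_max", min = n_spots_min)
  check_number(spot_radius_min, "spot_radius_min", min = 0.5)
  check_number(spot_radius_max, "spot_radius_max", min = spot_radius_min)
  if (spot_radius_max >= min(canvas_height, canvas_width) / 2) {
    abort("spot radii must be smaller than half the smallest canvas dimension")
  }
  structure(
    list(canvas_height = as.integer(canvas_height),
         canvas_width = as.integer(canvas_width),
         n_spots_min = as.integer(n_spots_min),
         n_spots_max = as.integer(n_spots_max),
         spot_radius_min = spot_radius_min,
         spot_radius_max = spot_radius_max,
         spot_shape = spot_shape, polarity = polarity),
    class = "pattern_spec")
}

#' @rdname pattern_spec
#' @export
pattern_spec_strip <- function() {
  pattern_spec(320, 1280, 16, 30, 12, 30, spot_shape = "elongated")
}

#' @rdname pattern_spec
#' @export
pattern_spec_belly <- function() {
  pattern_spec(960, 800, 20, 40, 12, 35, spot_shape = "round")
}

#' Specify capture-to-capture perturbations
#'
#' Capture parameters describe how a recapture image differs from the
#' individual's latent pattern: similarity-transform jitter (translation,
#' scale, rotation, crop offset), saturated glare blobs, per-spot
#' erosion/dilation, and sensor noise. All-zero parameters reproduce the
#' master pattern exactly. The `mild` preset emulates a consistently
#' photographed high-quality database; the `poor` preset emulates a
#' low-quality database with heavy glare and unstable spot shapes.
#'
#' @param translate_sd Translation jitter sd, pixels (per axis).
#' @param scale_sd Scale jitter sd (unitless, around 1).
#' @param rotate_sd Rotation jitter sd, degrees.
#' @param crop_offset_sd Additional crop-misalignment sd, pixels (per axis).
#' @param glare_count_mean Poisson mean of the number of glare blobs.
#' @param glare_radius Typical glare semi-axis, pixels.
#' @param spot_morph_prob Per-spot probability of 1-px erosion or dilation.
#' @param noise_sd Additive Gaussian noise sd, 8-bit intensity units.
#' @return A `capture_params` object (a validated list).
#' @export
capture_params <- function(translate_sd = 0, scale_sd = 0, rotate_sd = 0,
                           crop_offset_sd = 0, glare_count_mean = 0,
                           glare_radius = 0, spot_morph_prob = 0,
                           noise_sd = 0) {
  for (nm in c("translate_sd", "scale_sd", "rotate_sd", "crop_offset_sd",
               "glare_count_mean", "glare_radius", "noise_sd")) {
    check_number(get(nm), nm, min = 0)
  }
  check_number(spot_morph_prob, "spot_morph_prob", min = 0, max = 1)
  structure(
    list(translate_sd = translate_sd, scale_sd = scale_sd,
         rotate_sd = rotate_sd, crop_offset_sd = crop_offset_sd,
         glare_count_mean = glare_count_mean, glare_radius = glare_radius,
         spot_morph_prob = spot_morph_prob, noise_sd = noise_sd),
    class = "capture_params")
}

#' @rdname capture_params
#' @export
capture_params_mild <- function() {
  capture_params(translate_sd = 4, scale_sd = 0.015, rotate_sd = 0.8,
                 crop_offset_sd = 3, glare_count_mean = 0.5,
                 glare_radius = 30, spot_morph_prob = 0.15, noise_sd = 8)
}

#' @rdname capture_params
#' @export
capture_params_poor <- function() {
  capture_params(translate_sd = 8, scale_sd = 0.04, rotate_sd = 2,
                 crop_offset_sd = 6, glare_count_mean = 7,
                 glare_radius = 70, spot_morph_prob = 0.65, noise_sd = 22)
}

# rasterize one ellipse; returns linear indices into an H x W matrix
ellipse_indices <- function(H, W, cy, cx, a, b, phi) {
  rmax <- max(a, b)
  r1 <- max(1L, floor(cy - rmax)); r2 <- min(H, ceiling(cy + rmax))
  c1 <- max(1L, floor(cx - rmax)); c2 <- min(W, ceiling(cx + rmax))
  if (r1 > r2 || c1 > c2) return(integer(0))
  rs <- r1:r2; cs <- c1:c2
  dy <- rs - cy; dx <- cs - cx
  ct <- cos(phi); st <- sin(phi)
  # u along the major axis (columns for phi = 0), v across
  u <- outer(dy, dx, function(y, x) -st * y + ct * x)
  v <- outer(dy, dx, function(y, x) ct * y + st * x)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  ri <- rs[(idx - 1L) %% length(rs) + 1L]
  ci <- cs[(idx - 1L) %/% length(rs) + 1L]
  (ci - 1L) * H + ri
}

#' Generate the latent binary pattern of one individual
#'
#' Spots are placed uniformly at random; placements that would merge with an
#' already-placed spot are resampled a bounded number of times, so the number
#' of foreground components stays within the spec range unless the canvas is
#' too crowded (overlap merging may then reduce the count). Deterministic for
#' a fixed seed.
#'
#' @param spec A [pattern_spec()].
#' @param seed Integer seed.
#' @return An integer matrix with values `{0, 255}`; the attribute
#'   `foreground` gives the intensity of the spots.
#' @export
generate_individual <- function(spec, seed) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$canvas_height < 1 || spec$canvas_width < 1) {
    abort("degenerate pattern spec: zero canvas area")
  }
  withr::local_seed(seed)
  H <- spec$canvas_height; W <- spec$canvas_width
  fg <- if (spec$polarity == "dark_on_light") 0L else 255L
  bg <- 255L - fg
  n <- if (spec$n_spots_min == spec$n_spots_max) spec$n_spots_min
       else sample(spec$n_spots_min:spec$n_spots_max, 1L)

  mask <- matrix(FALSE, H, W)
  long_axis_phi <- if (W >= H) 0 else pi / 2
  for (k in seq_len(n)) {
    for (try in 1:60) {
      r <- runif(1, spec$spot_radius_min, spec$spot_radius_max)
      asp <- switch(spec$spot_shape,
                    round = 1,
                    elongated = runif(1, 1.8, 3.2),
                    stripe = runif(1, 3, 6))
      a <- r * sqrt(asp); b <- r / sqrt(asp)
      phi <- if (spec$spot_shape == "round") 0
             else long_axis_phi + rnorm(1, 0, 10 * pi / 180)
      cy <- if (H - 2 * a > 2) runif(1, 1 + a, H - a) else (H + 1) / 2
      cx <- if (W - 2 * a > 2) runif(1, 1 + a, W - a) else (W + 1) / 2
      idx <- ellipse_indices(H, W, cy, cx, a, b, phi)
      if (length(idx) == 0L) next
      # reject placements whose slightly dilated footprint touches existing
      # foreground (prevents component merging while space remains)
      halo <- ellipse_indices(H, W, cy, cx, a + 1.5, b + 1.5, phi)
      if (!any(mask[halo]) || try == 60L) {
        mask[idx] <- TRUE
        break
      }
    }
  }
  out <- matrix(bg, H, W)
  out[mask] <- fg
  out <- as_intensity(out, foreground = fg)
  attr(out, "polarity") <- spec$polarity
  out
}

# 1-px erosion/dilation of individual spots, worked on padded bounding boxes
morph_spots <- function(m, fg, bg, prob) {
  mask <- m == fg
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(m)
  act <- runif(nlab) < prob
  mode <- sample(c("erode", "dilate"), nlab, replace = TRUE)
  if (!any(act)) return(m)
  kern <- matrix(1, 3, 3)
  H <- nrow(m); W <- ncol(m)
  for (l in which(act)) {
    px <- which(lab == l)
    ri <- (px - 1L) %% H + 1L
    ci <- (px - 1L) %/% H + 1L
    r1 <- max(1L, min(ri) - 2L); r2 <- min(H, max(ri) + 2L)
    c1 <- max(1L, min(ci) - 2L); c2 <- min(W, max(ci) + 2L)
    sub <- matrix(0, r2 - r1 + 1L, c2 - c1 + 1L)
    sub[cbind(ri - r1 + 1L, ci - c1 + 1L)] <- 1
    sub2 <- if (mode[l] == "erode") EBImage::erode(sub, kern)
            else EBImage::dilate(sub, kern)
    block <- m[r1:r2, c1:c2]
    block[sub == 1 & sub2 == 0] <- bg
    block[sub2 == 1] <- fg
    m[r1:r2, c1:c2] <- block
  }
  m
}

#' Render a perturbed recapture of a master pattern
#'
#' Applies, in order: per-spot 1-px erosion/dilation on the binary master, a
#' sampled similarity transform (translation + crop offset, scale, rotation;
#' bilinear resampling), saturated elliptical glare blobs, additive Gaussian
#' noise, and clipping to the 8-bit range. With all parameters zero the
#' output equals the master exactly.
#'
#' @param master Binary master pattern from [generate_individual()].
#' @param params A [capture_params()].
#' @param seed Integer seed.
#' @return An integer intensity matrix of the same dimensions.
#' @export
render_capture <- function(master, params, seed) {
  stopifnot(inherits(params, "capture_params"))
  if (length(master) == 0L) abort("`master` must be a nonempty pattern")
  withr::local_seed(seed)
  fg <- attr(master, "foreground") %||% 0L
  bg <- 255L - fg
  m <- to_gray(master)

  dy <- rnorm(1, 0, params$translate_sd) + rnorm(1, 0, params$crop_offset_sd)
  dx <- rnorm(1, 0, params$translate_sd) + rnorm(1, 0, params$crop_offset_sd)
  s <- min(max(1 + rnorm(1, 0, params$scale_sd), 0.5), 2)
  th <- rnorm(1, 0, params$rotate_sd)

  if (params$spot_morph_prob > 0) {
    m <- morph_spots(m, fg, bg, params$spot_morph_prob)
  }
  m <- warp_similarity_cpp(m, s, th, dy, dx, fill = bg)

  ng <- rpois(1, params$glare_count_mean)
  if (ng > 0) {
    H <- nrow(m); W <- ncol(m)
    for (g in seq_len(ng)) {
      cy <- runif(1, 1, H); cx <- runif(1, 1, W)
      a <- params$glare_radius * runif(1, 0.6, 1.4)
      b <- params$glare_radius * runif(1, 0.6, 1.4)
      phi <- runif(1, 0, pi)
      m[ellipse_indices(H, W, cy, cx, a, b, phi)] <- 255
    }
  }
  if (params$noise_sd > 0) {
    m <- m + rnorm(length(m), 0, params$noise_sd)
  }
  as_intensity(m, foreground = fg)
}

#' Assemble a synthetic match database with known ground truth
#'
#' Generates `n_individuals` latent patterns and renders the requested number
#' of perturbed captures of each. Per-individual and per-capture seeds are
#' split deterministically from the master seed, so any record can be
#' regenerated independently. The known-pair list is exactly the set of
#' within-individual image pairs.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param captures_per_individual A single count, a vector of per-individual
#'   counts, or a `function(n)` returning one.
#' @param spec A [pattern_spec()].
#' @param params A [capture_params()].
#' @param seed Integer master seed.
#' @return A `match_db`: list with tibbles `captures` (`image_id`,
#'   `individual_id`, `capture_index`, `pattern` list-column) and `pairs`
#'   (`image_id_a`, `image_id_b`), plus the generating spec/params/seed.
#' @examples
#' db <- generate_database(3, 2, pattern_spec(60, 120, 6, 8, 4, 7, "round"),
#'                         capture_params_mild(), seed = 1)
#' glance(db)
#' @export
generate_database <- function(n_individuals, captures_per_individual = 2,
                              spec = pattern_spec_strip(),
                              params = capture_params_mild(), seed = 1) {
  check_number(n_individuals, "n_individuals", min = 1)
  n_individuals <- as.integer(n_individuals)
  withr::local_seed(seed)
  k <- if (is.function(captures_per_individual)) {
    captures_per_individual(n_individuals)
  } else if (length(captures_per_individual) == 1L) {
    rep(as.integer(captures_per_individual), n_individuals)
  } else {
    as.integer(captures_per_individual)
  }
  if (length(k) != n_individuals || any(k < 1L)) {
    abort("`captures_per_individual` must resolve to one count >= 1 per individual")
  }
  ind_seeds <- sample.int(2147483646L, n_individuals)
  rec_seeds <- sample.int(2147483646L, sum(k))

  rows <- vector("list", n_individuals)
  ri <- 0L
  for (i in seq_len(n_individuals)) {
    ind_id <- sprintf("ind%04d", i)
    master <- generate_individual(spec, ind_seeds[i])
    pats <- vector("list", k[i])
    for (j in seq_len(k[i])) {
      ri <- ri + 1L
      pats[[j]] <- render_capture(master, params, rec_seeds[ri])
    }
    rows[[i]] <- tibble(
      image_id = sprintf("%s_c%02d", ind_id, seq_len(k[i])),
      individual_id = ind_id,
      capture_index = seq_len(k[i]),
      pattern = pats)
  }
  captures <- dplyr::bind_rows(rows)
  match_database(captures, spec = spec, params = params, seed = seed)
}

#' Construct a match database from a capture table
#'
#' Lower-level constructor used by [generate_database()] and by the readers:
#' validates the manifest columns, checks id uniqueness and contiguous
#' capture indices, and (unless supplied) derives the known-pair list as all
#' within-individual image pairs.
#'
#' @param captures Tibble with columns `image_id`, `individual_id`,
#'   `capture_index`, and optionally a `pattern` list-column.
#' @param pairs Optional tibble (`image_id_a`, `image_id_b`); derived from
#'   `individual_id` when `NULL`.
#' @param spec,params,seed Optional provenance to store alongside.
#' @return A `match_db` object.
#' @export
match_database <- function(captures, pairs = NULL, spec = NULL, params = NULL,
                           seed = NULL) {
  captures <- as_tibble(captures)
  need <- c("image_id", "individual_id", "capture_index")
  if (!all(need %in% names(captures))) {
    abort("`captures` must have columns image_id, individual_id, capture_index")
  }
  if (anyDuplicated(captures$image_id)) {
    abort("duplicate image_id in capture table")
  }
  captures$capture_index <- as.integer(captures$capture_index)
  bad <- captures |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(ok = identical(sort(.data$capture_index),
                                    seq_along(.data$capture_index))) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort("capture_index must be contiguous (1..k) within each individual")
  }
  if (is.null(pairs)) {
    pairs <- captures |>
      dplyr::group_by(.data$individual_id) |>
      dplyr::group_map(function(g, key) {
        if (nrow(g) < 2) return(NULL)
        cmb <- combn(sort(g$image_id), 2)
        tibble(image_id_a = cmb[1, ], image_id_b = cmb[2, ])
      }) |>
      dplyr::bind_rows()
    if (nrow(pairs) == 0) {
      pairs <- tibble(image_id_a = character(), image_id_b = character())
    }
  } else {
    pairs <- as_tibble(pairs)
    unknown <- setdiff(c(pairs$image_id_a, pairs$image_id_b), captures$image_id)
    if (length(unknown) > 0) {
      abort(sprintf("pairs reference unknown image_id: %s",
                    paste(head(unknown, 3), collapse = ", ")))
    }
    if (any(pairs$image_id_a == pairs$image_id_b)) {
      abort("pairs must not contain self-pairs")
    }
  }
  structure(list(captures = captures, pairs = pairs, spec = spec,
                 params = params, seed = seed),
            class = "match_db")
}

#' @export
print.match_db <- function(x, ...) {
  cat(sprintf("<match_db> %d images, %d individuals, %d known pairs\n",
              nrow(x$captures), dplyr::n_distinct(x$captures$individual_id),
              nrow(x$pairs)))
  invisible(x)
}

#' @export
glance.match_db <- function(x, ...) {
  tibble(n_images = nrow(x$captures),
         n_individuals = dplyr::n_distinct(x$captures$individual_id),
         n_known_pairs = nrow(x$pairs),
         has_patterns = "pattern" %in% names(x$captures))
}
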