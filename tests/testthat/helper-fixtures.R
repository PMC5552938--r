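# small, fast fixture generators used across test files

to_mat <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

small_spec <- function(...) {
  args <- list(canvas_height = 64, canvas_width = 256, n_spots_min = 10,
               n_spots_max = 14, spot_radius_min = 4, spot_radius_max = 7,
               spot_shape = "round")
  args[names(list(...))] <- list(...)
  do.call(pattern_spec, args)
}

small_params <- function(...) {
  args <- list(translate_sd = 1.5, scale_sd = 0.01, rotate_sd = 0.5,
               crop_offset_sd = 1, noise_sd = 6)
  args[names(list(...))] <- list(...)
  do.call(capture_params, args)
}

# draw the same procedural texture in straightened (arc, normal) coordinates
# and along a curved spine, for the straightening reconstruction check
spine_texture <- function(s, u) {
  127.5 + 127.5 * sin(s / 12) * cos(u / 5)
}

make_curved_fixture <- function(H = 90, W = 60, band = 21, amp = 6,
                                period = 70) {
  # spine: gentle sine around the vertical centerline
  sr <- seq(5, H - 5, by = 0.25)
  sc <- W / 2 + amp * sin(2 * pi * sr / period)
  # arc length along the polyline
  dl <- sqrt(diff(sr)^2 + diff(sc)^2)
  arc <- c(0, cumsum(dl))

  img <- matrix(127.5, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      d2 <- (sr - r)^2 + (sc - c)^2
      k <- which.min(d2)
      # signed offset across the spine (normal points to +col for a mostly
      # vertical spine)
      tr <- if (k < length(sr)) c(sr[k + 1] - sr[k], sc[k + 1] - sc[k]) else
        c(sr[k] - sr[k - 1], sc[k] - sc[k - 1])
      tr <- tr / sqrt(sum(tr^2))
      u <- -(tr[2]) * (r - sr[k]) + tr[1] * (c - sc[k])
      if (abs(u) <= band) img[r, c] <- spine_texture(arc[k], u)
    }
  }
  straightened_ref <- outer(seq(0, max(arc), by = 1),
                            seq(-(band - 1) / 2, (band - 1) / 2),
                            spine_texture)
  vertices <- cbind(row = sr[seq(1, length(sr), by = 10)],
                    col = sc[seq(1, length(sr), by = 10)])
  list(image = img, spine = vertices, ref = straightened_ref, band = band)
}
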