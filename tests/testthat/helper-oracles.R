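# Independent brute-force oracles, written as plain loops directly from the
# score definitions. They deliberately share no code with the package
# internals beyond the documented sampling rule.

iround <- function(x) floor(x + 0.5)

# part tiling: remainder rows/cols to the last part
tile_parts <- function(H, W, pr, pc) {
  bh <- H %/% pr; bw <- W %/% pc
  out <- list()
  for (i in seq_len(pr)) {
    r0 <- (i - 1) * bh + 1
    h <- if (i == pr) H - r0 + 1 else bh
    for (j in seq_len(pc)) {
      c0 <- (j - 1) * bw + 1
      w <- if (j == pc) W - c0 + 1 else bw
      out[[length(out) + 1]] <- c(r0 = r0, c0 = c0, h = h, w = w)
    }
  }
  out
}

sad_oracle <- function(a, b, parts_rows, parts_cols, scales, max_translation,
                       min_overlap, max_intensity = 255, per_part = TRUE) {
  H <- nrow(a); W <- ncol(a); BH <- nrow(b); BW <- ncol(b)
  parts <- tile_parts(H, W, parts_rows, parts_cols)
  trans <- expand.grid(dr = -max_translation:max_translation,
                       dc = -max_translation:max_translation)
  if (per_part) {
    part_best <- numeric(length(parts))
    for (p in seq_along(parts)) {
      pp <- parts[[p]]
      cy <- pp["r0"] - 1 + (pp["h"] - 1) / 2
      cx <- pp["c0"] - 1 + (pp["w"] - 1) / 2
      best <- -1
      for (s in scales) for (t in seq_len(nrow(trans))) {
        sad <- 0; cnt <- 0
        for (i in 0:(pp["h"] - 1)) for (j in 0:(pp["w"] - 1)) {
          br <- iround(cy + (i - (pp["h"] - 1) / 2 + trans$dr[t]) * s)
          bc <- iround(cx + (j - (pp["w"] - 1) / 2 + trans$dc[t]) * s)
          if (br >= 0 && br < BH && bc >= 0 && bc < BW) {
            sad <- sad + abs(a[pp["r0"] + i, pp["c0"] + j] - b[br + 1, bc + 1])
            cnt <- cnt + 1
          }
        }
        if (cnt == 0 || cnt / (pp["h"] * pp["w"]) < min_overlap) next
        sim <- 1 - sad / (cnt * max_intensity)
        if (sim > best) best <- sim
      }
      part_best[p] <- max(best, 0)
    }
    return(mean(part_best))
  }
  # global mode: one transform shared by all parts
  best_total <- 0
  for (s in scales) for (t in seq_len(nrow(trans))) {
    sims <- numeric(length(parts))
    for (p in seq_along(parts)) {
      pp <- parts[[p]]
      cy <- pp["r0"] - 1 + (pp["h"] - 1) / 2
      cx <- pp["c0"] - 1 + (pp["w"] - 1) / 2
      sad <- 0; cnt <- 0
      for (i in 0:(pp["h"] - 1)) for (j in 0:(pp["w"] - 1)) {
        br <- iround(cy + (i - (pp["h"] - 1) / 2 + trans$dr[t]) * s)
        bc <- iround(cx + (j - (pp["w"] - 1) / 2 + trans$dc[t]) * s)
        if (br >= 0 && br < BH && bc >= 0 && bc < BW) {
          sad <- sad + abs(a[pp["r0"] + i, pp["c0"] + j] - b[br + 1, bc + 1])
          cnt <- cnt + 1
        }
      }
      if (cnt == 0 || cnt / (pp["h"] * pp["w"]) < min_overlap) {
        sims[p] <- 0
      } else {
        sims[p] <- 1 - sad / (cnt * max_intensity)
      }
    }
    if (mean(sims) > best_total) best_total <- mean(sims)
  }
  best_total
}

# ITM oracle: patch NCC is the Pearson correlation between the patch and the
# candidate window, so stats::cor serves as the independent reference
itm_oracle <- function(a, b, patch_rows, patch_cols, margin,
                       constant_score = 0) {
  H <- nrow(a); W <- ncol(a)
  parts <- tile_parts(H, W, patch_rows, patch_cols)
  total <- 0
  for (pp in parts) {
    av <- as.vector(a[pp["r0"]:(pp["r0"] + pp["h"] - 1),
                      pp["c0"]:(pp["c0"] + pp["w"] - 1)])
    if (stats::var(av) <= 1e-12 / (length(av) - 1)) {
      total <- total + constant_score
      next
    }
    best <- -Inf
    for (dr in -margin:margin) for (dc in -margin:margin) {
      r0 <- pp["r0"] + dr; c0 <- pp["c0"] + dc
      if (r0 < 1 || c0 < 1 || r0 + pp["h"] - 1 > nrow(b) ||
          c0 + pp["w"] - 1 > ncol(b)) next
      bv <- as.vector(b[r0:(r0 + pp["h"] - 1), c0:(c0 + pp["w"] - 1)])
      if (stats::var(bv) <= 1e-12 / (length(bv) - 1)) next
      r <- stats::cor(av, bv)
      if (r > best) best <- r
    }
    total <- total + if (is.finite(best)) best else constant_score
  }
  total
}

# sort-and-scan rank oracle on a named score vector for one query
rank_oracle <- function(scores_q, match_id, excluded = character()) {
  s_match <- scores_q[[match_id]]
  cand <- scores_q[setdiff(names(scores_q), c(match_id, excluded))]
  ord <- sort(unname(cand), decreasing = TRUE)
  r <- 1L
  for (v in ord) {
    if (v >= s_match) r <- r + 1L else break
  }
  r
}

# random similarity table over a toy database (no patterns needed)
random_table_db <- function(n_individuals, n_singletons, seed,
                            captures = 2L) {
  withr::local_seed(seed)
  caps <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_individuals), function(i) {
      tibble::tibble(image_id = sprintf("p%03d_%d", i, seq_len(captures)),
                     individual_id = sprintf("p%03d", i),
                     capture_index = seq_len(captures))
    }),
    tibble::tibble(image_id = sprintf("s%03d_1", seq_len(n_singletons)),
                   individual_id = sprintf("s%03d", seq_len(n_singletons)),
                   capture_index = 1L))
  db <- match_database(caps)
  ids <- caps$image_id
  n <- length(ids)
  ia <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- sequence((n - 1L):1L, from = 2:n)
  sc <- runif(length(ia))
  # nudge true pairs upward so ranks are non-trivial but not perfect
  key <- paste(caps$individual_id[ia], caps$individual_id[ib])
  same <- caps$individual_id[ia] == caps$individual_id[ib]
  sc[same] <- sc[same] + runif(sum(same), -0.2, 0.6)
  tab <- tibble::tibble(image_id_a = ids[ia], image_id_b = ids[ib], score = sc)
  list(db = db, table = spotmatch:::new_similarity_tbl(tab, "random"))
}
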