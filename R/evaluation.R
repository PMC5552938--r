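#' Score all image pairs of a database
#'
#' Prepares every pattern once with the matcher's preparation step, then
#' scores all `N (N - 1) / 2` unordered pairs (first id is the query
#' direction). Pairs on which the matcher fails score `NA` and are reported;
#' ranking treats missing scores as `-Inf`. An optional CSV checkpoint makes
#' long runs resumable.
#'
#' @param db A `match_db` (see [generate_database()], [match_database()]).
#' @param matcher A matcher object (see [matchers]).
#' @param checkpoint Optional path to a CSV checkpoint; completed pairs are
#'   reloaded from it and new scores appended every `checkpoint_every` pairs.
#' @param checkpoint_every Flush interval for the checkpoint file.
#' @return A `similarity_tbl`: tibble (`image_id_a`, `image_id_b`, `score`)
#'   with attributes `algorithm` and `image_ids`.
#' @export
all_pairs_scores <- function(db, matcher, checkpoint = NULL,
                             checkpoint_every = 500L) {
  stopifnot(inherits(db, "match_db"), inherits(matcher, "pattern_matcher"))
  caps <- db$captures
  if (nrow(caps) < 2) abort("at least 2 images are required")
  if (!"pattern" %in% names(caps)) abort("database carries no patterns")
  ids <- caps$image_id
  n <- length(ids)

  reps <- lapply(caps$pattern, function(p) {
    tryCatch(matcher$prepare(p), error = function(e) NULL)
  })
  names(reps) <- ids

  ia <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- sequence((n - 1L):1L, from = 2:n)
  out <- tibble(image_id_a = ids[ia], image_id_b = ids[ib],
                score = NA_real_)

  done <- rep(FALSE, nrow(out))
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- readr::read_csv(checkpoint, show_col_types = FALSE)
    key <- paste(out$image_id_a, out$image_id_b)
    hit <- match(paste(prev$image_id_a, prev$image_id_b), key)
    ok <- !is.na(hit)
    out$score[hit[ok]] <- prev$score[ok]
    done[hit[ok]] <- TRUE
  }

  since_flush <- 0L
  for (p in which(!done)) {
    ra <- reps[[out$image_id_a[p]]]
    rb <- reps[[out$image_id_b[p]]]
    out$score[p] <- if (is.null(ra) || is.null(rb)) NA_real_ else {
      tryCatch(matcher$score(ra, rb), error = function(e) NA_real_)
    }
    since_flush <- since_flush + 1L
    if (!is.null(checkpoint) && since_flush >= checkpoint_every) {
      readr::write_csv(out[done | seq_len(nrow(out)) <= p, ], checkpoint)
      since_flush <- 0L
    }
  }
  if (!is.null(checkpoint)) readr::write_csv(out, checkpoint)
  n_missing <- sum(is.na(out$score))
  if (n_missing > 0) {
    warn(sprintf("%d pair(s) have missing scores (matcher failure); treated as -Inf in ranking",
                 n_missing))
  }
  new_similarity_tbl(out, algorithm = matcher$name, image_ids = ids)
}

new_similarity_tbl <- function(tbl, algorithm = NA_character_,
                               image_ids = NULL) {
  tbl <- as_tibble(tbl)
  if (is.null(image_ids)) {
    image_ids <- sort(unique(c(tbl$image_id_a, tbl$image_id_b)))
  }
  structure(tbl, algorithm = algorithm, image_ids = image_ids,
            class = c("similarity_tbl", class(tbl)))
}

# dense symmetric lookup matrix; NA scores become -Inf, diagonal NA
score_matrix <- function(table) {
  ids <- attr(table, "image_ids") %||%
    sort(unique(c(table$image_id_a, table$image_id_b)))
  n <- length(ids)
  m <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  ia <- match(table$image_id_a, ids)
  ib <- match(table$image_id_b, ids)
  sc <- ifelse(is.na(table$score), -Inf, table$score)
  m[cbind(ia, ib)] <- sc
  m[cbind(ib, ia)] <- sc
  diag(m) <- NA_real_
  m
}

#' Retrieved rank of a known match
#'
#' The rank of `match_id` for query `query_id` is 1 plus the number of
#' candidate images (excluding the query, the match, and `excluded_ids`)
#' whose similarity to the query is greater than or equal to the match's
#' score — ties are counted against the match (pessimistic tie policy, so
#' recognition is never overstated). A rank of 1 means the known match is
#' the top-ranked image.
#'
#' @param query_id,match_id Image ids present in `table`.
#' @param table A `similarity_tbl` from [all_pairs_scores()] or
#'   [read_scores()].
#' @param excluded_ids Ids removed from the candidate set (e.g. other
#'   captures of the query individual).
#' @return Integer rank >= 1.
#' @export
rank_of_match <- function(query_id, match_id, table, excluded_ids = character()) {
  ids <- attr(table, "image_ids") %||%
    sort(unique(c(table$image_id_a, table$image_id_b)))
  if (!query_id %in% ids || !match_id %in% ids) {
    abort("query_id and match_id must both be present in the score table")
  }
  if (match_id %in% excluded_ids) abort("match_id must not be excluded")
  qa <- table$image_id_a == query_id | table$image_id_b == query_id
  other <- ifelse(table$image_id_a[qa] == query_id,
                  table$image_id_b[qa], table$image_id_a[qa])
  sc <- ifelse(is.na(table$score[qa]), -Inf, table$score[qa])
  s_match <- sc[other == match_id]
  if (length(s_match) != 1L) abort("no score recorded for the query/match pair")
  keep <- !(other %in% c(excluded_ids, match_id))
  1L + sum(sc[keep] >= s_match)
}

#' Ranks of designated matches for every eligible query
#'
#' Evaluates recognition the way a capture-recapture operator would: every
#' image of an individual with at least `k + 1` captures is used as a query;
#' its `k` designated matching images are the individual's other captures in
#' capture order; all remaining captures of that individual are excluded
#' from the candidate set so exactly `k` matching images compete. The
#' retrieved rank of the query is the minimum over its `k` matches of the
#' single-match rank (other designated matches are excluded while ranking
#' each one).
#'
#' @param db A `match_db`.
#' @param table A `similarity_tbl` over the database images.
#' @param k Number of matching images available per query.
#' @return Tibble (`image_id`, `individual_id`, `rank`, `k`).
#' @export
match_ranks <- function(db, table, k = 1L) {
  stopifnot(inherits(db, "match_db"))
  check_number(k, "k", min = 1)
  caps <- db$captures
  m <- score_matrix(table)
  ids <- rownames(m)
  eligible <- caps |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(dplyr::n() >= k + 1) |>
    dplyr::ungroup()
  if (nrow(eligible) == 0) {
    abort(sprintf("no individual has at least %d captures", k + 1))
  }
  by_ind <- split(eligible[order(eligible$capture_index), ],
                  eligible$individual_id[order(eligible$capture_index)])
  res <- lapply(by_ind, function(g) {
    gid <- g$image_id
    ranks <- vapply(seq_along(gid), function(qi) {
      q <- gid[qi]
      others <- setdiff(gid, q)
      matches <- others[seq_len(k)]       # first k other captures
      sq <- m[q, ]
      min(vapply(matches, function(mt) {
        excl <- setdiff(gid, c(q, mt))    # all other captures of the individual
        cand <- setdiff(ids, c(q, mt, excl))
        1L + sum(sq[cand] >= sq[mt])
      }, integer(1)))
    }, integer(1))
    tibble(image_id = gid, individual_id = g$individual_id[1], rank = ranks,
           k = as.integer(k))
  })
  dplyr::bind_rows(res)
}

#' Rank cumulative match curve
#'
#' `cdf(r)` is the fraction of evaluated queries (or known pairs) whose
#' retrieved rank is `r` or better; `frr = 1 - cdf` is the false rejection
#' rate when the top `r` ranked images are reviewed.
#'
#' @param ranks Integer vector of retrieved ranks, or the tibble returned by
#'   [match_ranks()].
#' @param r_max Largest rank tabulated (defaults to `max(ranks)`).
#' @param db_size,matches_per_query,replicates Optional metadata stored on
#'   the result.
#' @return A `rank_cdf` tibble (`r`, `cdf`, `frr`) with metadata attributes
#'   `n_pairs`, `db_size`, `matches_per_query`, `replicates`.
#' @examples
#' rank_cdf(c(1, 2, 10), r_max = 10)
#' @export
rank_cdf <- function(ranks, r_max = NULL, db_size = NA_integer_,
                     matches_per_query = NA_integer_, replicates = 1L) {
  if (is.data.frame(ranks)) {
    if (!is.na(matches_per_query) && "k" %in% names(ranks)) {
      # keep explicit argument
    } else if ("k" %in% names(ranks)) {
      matches_per_query <- ranks$k[1]
    }
    ranks <- ranks$rank
  }
  if (length(ranks) == 0) abort("`ranks` must be nonempty")
  r_max <- as.integer(r_max %||% max(ranks))
  r <- seq_len(r_max)
  cdf <- vapply(r, function(ri) mean(ranks <= ri), numeric(1))
  new_rank_cdf(tibble(r = r, cdf = cdf, frr = 1 - cdf),
               n_pairs = length(ranks), db_size = db_size,
               matches_per_query = matches_per_query,
               replicates = replicates)
}

new_rank_cdf <- function(tbl, n_pairs, db_size, matches_per_query,
                         replicates) {
  structure(as_tibble(tbl), n_pairs = as.integer(n_pairs),
            db_size = db_size, matches_per_query = matches_per_query,
            replicates = as.integer(replicates),
            class = c("rank_cdf", class(as_tibble(tbl))))
}

#' Evaluate a rank CDF (or its complement) at a rank
#'
#' @param cdf A `rank_cdf`.
#' @param r Rank at which to evaluate.
#' @return `cdf_at()` returns `cdf(r)`; `frr()` returns `1 - cdf(r)`, the
#'   false rejection rate when reviewing the top `r` ranks.
#' @export
cdf_at <- function(cdf, r) {
  stopifnot(inherits(cdf, "rank_cdf"))
  check_number(r, "r", min = 1)
  below <- cdf$r <= r
  if (!any(below)) return(0)
  cdf$cdf[max(which(below))]
}

#' @rdname cdf_at
#' @export
frr <- function(cdf, r) 1 - cdf_at(cdf, r)

#' Recognition versus database size by pair-retained subsampling
#'
#' Re-evaluates the rank CDF on randomly subsampled databases. Within each
#' replicate the evaluated individuals (queries and their designated
#' matches) are always retained and the remaining images act as a distractor
#' pool sampled without replacement; across the requested sizes the draws
#' are nested, so each query's rank is monotone in the database size and the
#' replicate-averaged `cdf(r)` is nonincreasing with size. At `size` equal
#' to the full database every replicate reproduces the full-database CDF
#' exactly. The `"literal"` mode instead samples `size` images uniformly and
#' evaluates only the pairs that survive by chance.
#'
#' @param db A `match_db`.
#' @param table A `similarity_tbl` over the full database.
#' @param sizes Database sizes to evaluate (each between the retained
#'   minimum and the full size).
#' @param reps Number of random replicates per size (averaged).
#' @param r_max Largest tabulated rank.
#' @param seed Seed for the distractor draws.
#' @param mode `"retain_pairs"` (default) or `"literal"`.
#' @param k Matches available per query (see [match_ranks()]).
#' @return A `subsample_cdf` tibble (`db_size`, `r`, `cdf`, `frr`,
#'   `n_pairs`, `reps`).
#' @export
subsample_cdf <- function(db, table, sizes, reps = 50L, r_max = 10L,
                          seed = 1L, mode = c("retain_pairs", "literal"),
                          k = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "match_db"))
  caps <- db$captures
  n_full <- nrow(caps)
  sizes <- sort(as.integer(sizes))
  if (any(sizes > n_full)) abort("subsample sizes exceed the database size")
  m <- score_matrix(table)
  ids <- rownames(m)

  eligible <- caps |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(dplyr::n() >= k + 1) |>
    dplyr::ungroup()
  retained <- eligible$image_id
  pool <- setdiff(ids, retained)
  if (mode == "retain_pairs" && any(sizes < length(retained))) {
    abort(sprintf("sizes must be >= %d (images retained by the evaluated pairs)",
                  length(retained)))
  }

  # per-query precomputation: match score and, over the distractor pool,
  # which images beat it (ties count against the match)
  queries <- match_ranks(db, table, k = k)
  qinfo <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries$image_id[i]
    g <- eligible$image_id[eligible$individual_id == queries$individual_id[i]]
    gq <- setdiff(g, q)
    matches <- gq[seq_len(k)]
    sq <- m[q, ]
    best <- lapply(matches, function(mt) {
      cand_ret <- setdiff(retained, g)     # retained competitors
      list(s = sq[mt],
           base = sum(sq[cand_ret] >= sq[mt]),
           beats = sq[pool] >= sq[mt])
    })
    best
  })

  withr::local_seed(seed)
  acc <- list()
  for (rep_i in seq_len(reps)) {
    perm <- if (length(pool) > 0) sample(pool) else character(0)
    for (sz in sizes) {
      if (mode == "retain_pairs") {
        n_extra <- sz - length(retained)
        drawn_mask <- rep(FALSE, length(pool))
        if (n_extra > 0) drawn_mask[match(perm[seq_len(n_extra)], pool)] <- TRUE
        ranks <- vapply(qinfo, function(qb) {
          min(vapply(qb, function(alt) {
            1L + alt$base + sum(alt$beats & drawn_mask)
          }, integer(1)))
        }, integer(1))
        n_pairs <- length(ranks)
      } else {
        subset_ids <- sample(ids, sz)
        keep_q <- vapply(seq_len(nrow(queries)), function(i) {
          q <- queries$image_id[i]
          g <- eligible$image_id[eligible$individual_id == queries$individual_id[i]]
          gq <- setdiff(g, q)[seq_len(k)]
          q %in% subset_ids && all(gq %in% subset_ids)
        }, logical(1))
        if (!any(keep_q)) next
        ranks <- vapply(which(keep_q), function(i) {
          q <- queries$image_id[i]
          g <- eligible$image_id[eligible$individual_id == queries$individual_id[i]]
          gq <- setdiff(g, q)
          matches <- gq[seq_len(k)]
          sq <- m[q, ]
          min(vapply(matches, function(mt) {
            cand <- setdiff(intersect(subset_ids, ids), c(q, g))
            1L + sum(sq[cand] >= sq[mt])
          }, integer(1)))
        }, integer(1))
        n_pairs <- length(ranks)
      }
      cdfv <- vapply(seq_len(r_max), function(ri) mean(ranks <= ri), numeric(1))
      key <- as.character(sz)
      if (is.null(acc[[key]])) acc[[key]] <- list(cdf = cdfv * 0, n = 0L, np = 0L)
      acc[[key]]$cdf <- acc[[key]]$cdf + cdfv
      acc[[key]]$n <- acc[[key]]$n + 1L
      acc[[key]]$np <- acc[[key]]$np + n_pairs
    }
  }
  out <- purrr::map_dfr(names(acc), function(key) {
    a <- acc[[key]]
    tibble(db_size = as.integer(key), r = seq_len(r_max),
           cdf = a$cdf / a$n, frr = 1 - a$cdf / a$n,
           n_pairs = a$np / a$n, reps = a$n)
  })
  structure(out, class = c("subsample_cdf", class(out)),
            matches_per_query = as.integer(k), mode = mode)
}

#' Recognition with multiple matching images in the database
#'
#' With `k` matching images available per query the retrieved rank is the
#' best (minimum) rank among them, so the multi-match CDF dominates the
#' single-match CDF pointwise.
#'
#' @param db A `match_db` containing individuals with at least `k + 1`
#'   captures.
#' @param table A `similarity_tbl`.
#' @param k Matching images available per query.
#' @param r_max Largest tabulated rank.
#' @return A `rank_cdf`.
#' @export
multi_match_cdf <- function(db, table, k, r_max = 10L) {
  ranks <- match_ranks(db, table, k = k)
  rank_cdf(ranks, r_max = r_max, db_size = nrow(db$captures),
           matches_per_query = as.integer(k))
}

#' Processing-time cost model for matching a database
#'
#' Manual matching compares all `N (N - 1) / 2` image pairs; computer-aided
#' matching preprocesses each image once and reviews the top `r_review`
#' ranked candidates per image, so its cost grows linearly in `N`.
#'
#' @param n Database size(s).
#' @param t_compare Seconds per manual pair comparison.
#' @param t_prep Seconds of manual preprocessing per image.
#' @param r_review Number of top-ranked images reviewed per query.
#' @return Hours (vectorized over `n`); `matching_cost()` returns a tibble
#'   with both columns.
#' @examples
#' manual_hours(100)          # 1.375
#' computer_aided_hours(100)  # 1.11
#' @export
manual_hours <- function(n, t_compare = 1) {
  n * (n - 1) / 2 * t_compare / 3600
}

#' @rdname manual_hours
#' @export
computer_aided_hours <- function(n, t_prep = 30, r_review = 10, t_compare = 1) {
  (n * t_prep + n * r_review * t_compare) / 3600
}

#' @rdname manual_hours
#' @export
matching_cost <- function(n, t_compare = 1, t_prep = 30, r_review = 10) {
  tibble(n = n,
         manual_hours = manual_hours(n, t_compare),
         computer_aided_hours = computer_aided_hours(n, t_prep, r_review,
                                                     t_compare))
}
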