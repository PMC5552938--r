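# cheap matcher for structural tests: mean absolute intensity difference
matcher_meandiff <- function() {
  spotmatch:::new_matcher("meandiff",
                          prepare = function(p) mean(p),
                          score = function(a, b) 1 - abs(a - b) / 255)
}

test_that("all_pairs_scores covers exactly N(N-1)/2 pairs", {
  for (n_ind in c(1, 10, 50)) {
    db <- generate_database(max(n_ind, 1), 2, small_spec(), capture_params(),
                            seed = 1)
    tab <- all_pairs_scores(db, matcher_meandiff())
    n <- nrow(db$captures)
    expect_equal(nrow(tab), n * (n - 1) / 2)
    expect_false(any(tab$image_id_a == tab$image_id_b))
  }
})

test_that("all_pairs_scores checkpoints are resumable and lossless", {
  db <- generate_database(6, 2, small_spec(), small_params(), seed = 2)
  ck <- withr::local_tempfile(fileext = ".csv")
  full <- all_pairs_scores(db, matcher_meandiff())
  partial <- tibble::as_tibble(full)[1:20, ]
  readr::write_csv(partial, ck)
  resumed <- all_pairs_scores(db, matcher_meandiff(), checkpoint = ck)
  expect_equal(tibble::as_tibble(resumed), tibble::as_tibble(full))
  on_disk <- readr::read_csv(ck, show_col_types = FALSE)
  expect_equal(nrow(on_disk), nrow(full))
})

test_that("rank_of_match follows the pessimistic-tie counting rule", {
  ids <- c("q", "m", "c1", "c2", "c3", "c4")
  caps <- tibble::tibble(image_id = ids,
                         individual_id = c("x", "x", "a", "b", "c", "d"),
                         capture_index = c(1L, 2L, 1L, 1L, 1L, 1L))
  mk_tab <- function(scores) {
    cmb <- t(combn(ids, 2))
    tab <- tibble::tibble(image_id_a = cmb[, 1], image_id_b = cmb[, 2],
                          score = 0)
    for (nm in names(scores)) {
      hit <- (tab$image_id_a == "q" & tab$image_id_b == nm) |
        (tab$image_id_b == "q" & tab$image_id_a == nm)
      tab$score[hit] <- scores[[nm]]
    }
    spotmatch:::new_similarity_tbl(tab)
  }
  # match strictly above all distractors -> rank 1
  t1 <- mk_tab(list(m = 0.99, c1 = 0.5, c2 = 0.4, c3 = 0.3, c4 = 0.2))
  expect_equal(rank_of_match("q", "m", t1), 1)
  # one distractor above -> rank 2
  t2 <- mk_tab(list(m = 0.9, c1 = 0.95, c2 = 0.8, c3 = 0.7, c4 = 0.6))
  expect_equal(rank_of_match("q", "m", t2), 2)
  # tie with one distractor counts against the match -> rank 2
  t3 <- mk_tab(list(m = 0.9, c1 = 0.9, c2 = 0.1, c3 = 0.1, c4 = 0.1))
  expect_equal(rank_of_match("q", "m", t3), 2)
  # exclusions shrink the candidate set
  expect_equal(rank_of_match("q", "m", t2, excluded_ids = "c1"), 1)
  expect_error(rank_of_match("q", "zz", t1), "present in the score table")
})

test_that("rank_of_match agrees with the sort-and-scan oracle on random tables", {
  set.seed(11)
  for (i in 1:20) {
    n_ind <- sample(3:10, 1)
    rt <- random_table_db(n_ind, sample(5:20, 1), seed = i)
    m <- spotmatch:::score_matrix(rt$table)
    pr <- rt$db$pairs[sample(nrow(rt$db$pairs), 1), ]
    q <- pr$image_id_a; mt <- pr$image_id_b
    scores_q <- m[q, setdiff(colnames(m), q)]
    expect_identical(rank_of_match(q, mt, rt$table),
                     rank_oracle(scores_q, mt))
  }
})

test_that("rank_cdf tabulates the cumulative recognition curve", {
  cdf <- rank_cdf(c(1, 2, 10), r_max = 10)
  expect_equal(cdf_at(cdf, 1), 1 / 3)
  expect_equal(cdf_at(cdf, 9), 2 / 3)
  expect_equal(cdf_at(cdf, 10), 1)
  all1 <- rank_cdf(rep(1, 8), r_max = 5)
  expect_true(all(all1$cdf == 1))
  # 19 of 20 ranks at 5 or better
  cdf20 <- rank_cdf(c(rep(1, 10), rep(3, 5), rep(5, 4), 12), r_max = 12)
  expect_equal(cdf_at(cdf20, 5), 0.95)
  expect_error(rank_cdf(integer(0)), "nonempty")
})

test_that("frr is identically 1 - cdf and cdf is nondecreasing", {
  set.seed(12)
  for (i in 1:10) {
    ranks <- sample(1:30, 40, replace = TRUE)
    cdf <- rank_cdf(ranks, r_max = 30)
    expect_true(all(diff(cdf$cdf) >= 0))
    expect_true(all(cdf$cdf >= 0 & cdf$cdf <= 1))
    expect_equal(cdf$frr, 1 - cdf$cdf)
    expect_equal(frr(cdf, 10), 1 - cdf_at(cdf, 10))
    expect_equal(cdf_at(cdf, 30), 1)
  }
})

test_that("multi-match retrieval takes the best rank and dominates single-match", {
  rt <- random_table_db(6, 10, seed = 5, captures = 4L)
  c1 <- multi_match_cdf(rt$db, rt$table, k = 1, r_max = 15)
  c3 <- multi_match_cdf(rt$db, rt$table, k = 3, r_max = 15)
  expect_true(all(c3$cdf >= c1$cdf))
  # k = 1 equals the plain single-match evaluation
  mr <- match_ranks(rt$db, rt$table, k = 1)
  expect_equal(tidy(c1), tidy(rank_cdf(mr, r_max = 15)))
  # the min-over-matches rule, checked directly on one query
  q <- mr$image_id[1]
  g <- rt$db$captures$image_id[rt$db$captures$individual_id == mr$individual_id[1]]
  singles <- vapply(setdiff(g, q)[1:3], function(mt) {
    rank_of_match(q, mt, rt$table, excluded_ids = setdiff(g, c(q, mt)))
  }, integer(1))
  mr3 <- match_ranks(rt$db, rt$table, k = 3)
  expect_equal(mr3$rank[mr3$image_id == q], min(singles))
})

test_that("subsampling at the full size reproduces the full-database CDF exactly", {
  rt <- random_table_db(8, 30, seed = 6)
  n <- nrow(rt$db$captures)
  full <- multi_match_cdf(rt$db, rt$table, k = 1, r_max = 10)
  sub <- subsample_cdf(rt$db, rt$table, sizes = n, reps = 3, r_max = 10,
                       seed = 1)
  expect_equal(sub$cdf, full$cdf)
})

test_that("pair-retained subsampled cdf is nonincreasing in database size", {
  rt <- random_table_db(8, 60, seed = 7)
  sub <- subsample_cdf(rt$db, rt$table, sizes = c(20, 40, 60, 76), reps = 10,
                       r_max = 10, seed = 2)
  for (r in unique(sub$r)) {
    v <- sub$cdf[sub$r == r][order(unique(sub$db_size))]
    expect_true(all(diff(v) <= 1e-12))
  }
  expect_error(subsample_cdf(rt$db, rt$table, sizes = 3, reps = 2),
               "sizes must be >=")
  expect_error(subsample_cdf(rt$db, rt$table, sizes = 1000, reps = 2),
               "exceed")
})

test_that("literal-mode subsampling evaluates only surviving pairs", {
  rt <- random_table_db(10, 40, seed = 8)
  sub <- subsample_cdf(rt$db, rt$table, sizes = c(30, 60), reps = 5,
                       r_max = 10, seed = 3, mode = "literal")
  expect_true(all(sub$cdf >= 0 & sub$cdf <= 1))
  expect_lt(sub$n_pairs[sub$db_size == 30][1],
            nrow(rt$db$pairs) * 2)
})

test_that("the processing-time cost model matches its closed form", {
  expect_equal(manual_hours(100), 1.375)
  expect_equal(manual_hours(1), 0)
  expect_equal(manual_hours(1000), 138.75)
  expect_equal(computer_aided_hours(100), 100 * 40 / 3600)
  expect_equal(computer_aided_hours(10000), 10000 * 40 / 3600)
  expect_equal(computer_aided_hours(500, t_prep = 0, r_review = 0), 0)
  tbl <- matching_cost(c(100, 1000))
  expect_equal(tbl$manual_hours, c(1.375, 138.75))
  expect_equal(tbl$computer_aided_hours, c(100, 1000) * 40 / 3600)
})
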