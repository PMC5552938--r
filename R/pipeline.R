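#' Configure an end-to-end benchmarking run
#'
#' A run config fully determines a pipeline run: database generation
#' settings, the algorithms to score, evaluation settings, and one master
#' seed. Configs serialize to YAML ([write_run_config()] /
#' [read_run_config()]) and a config re-run with the same seed reproduces
#' identical outputs.
#'
#' @param n_individuals,captures_per_individual,spec,params,seed Database
#'   generation settings (see [generate_database()]).
#' @param algorithms Character vector among `"sad"`, `"itm-binary"`,
#'   `"itm-color"`, `"feature-geo"`, `"feature-points"`.
#' @param r_max Largest tabulated rank.
#' @param sizes Optional database sizes for subsampled CDFs.
#' @param reps Replicates per subsampled size.
#' @param k_values Matches-per-query values to evaluate (those exceeding the
#'   available captures are rejected at validation).
#' @param write_images Write capture PNGs into the run directory.
#' @param cost_sizes Database sizes for the processing-time cost table.
#' @return A `run_config` object.
#' @export
run_config <- function(n_individuals = 30, captures_per_individual = 2,
                       spec = pattern_spec_strip(),
                       params = capture_params_mild(),
                       algorithms = c("sad", "itm-binary"),
                       r_max = 10, sizes = NULL, reps = 50, k_values = 1,
                       write_images = FALSE,
                       cost_sizes = c(100, 500, 1000, 5000, 10000),
                       seed = 1) {
  known <- c("sad", "itm-binary", "itm-color", "feature-geo", "feature-points")
  bad <- setdiff(algorithms, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown algorithm(s): %s", paste(bad, collapse = ", ")))
  }
  stopifnot(inherits(spec, "pattern_spec"), inherits(params, "capture_params"))
  n_images <- if (length(captures_per_individual) == 1L &&
                  !is.function(captures_per_individual)) {
    n_individuals * captures_per_individual
  } else if (is.numeric(captures_per_individual)) {
    sum(captures_per_individual)
  } else {
    NA_integer_
  }
  if (!is.null(sizes) && !is.na(n_images) && any(sizes > n_images)) {
    abort("subsample sizes exceed the database size")
  }
  kmax <- if (is.numeric(captures_per_individual)) {
    max(captures_per_individual)
  } else {
    NA_integer_
  }
  if (!is.na(kmax) && any(k_values > kmax - 1)) {
    abort("k_values exceed the available captures per individual")
  }
  structure(list(n_individuals = n_individuals,
                 captures_per_individual = captures_per_individual,
                 spec = spec, params = params, algorithms = algorithms,
                 r_max = as.integer(r_max), sizes = sizes,
                 reps = as.integer(reps), k_values = as.integer(k_values),
                 write_images = isTRUE(write_images),
                 cost_sizes = cost_sizes, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- config
  x$spec <- unclass(x$spec)
  x$params <- unclass(x$params)
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(n_individuals = x$n_individuals,
             captures_per_individual = x$captures_per_individual,
             spec = do.call(pattern_spec, x$spec),
             params = do.call(capture_params, x$params),
             algorithms = x$algorithms, r_max = x$r_max, sizes = x$sizes,
             reps = x$reps, k_values = x$k_values,
             write_images = x$write_images, cost_sizes = x$cost_sizes,
             seed = x$seed)
}

resolve_matcher <- function(name) {
  switch(name,
         "sad" = matcher_sad(),
         "itm-binary" = matcher_itm(itm_config(mode = "binary")),
         "itm-color" = matcher_itm(itm_config(mode = "color")),
         "feature-geo" = matcher_feature_geo(),
         "feature-points" = matcher_feature_points(),
         abort(sprintf("unknown algorithm: %s", name)))
}

#' Run the full generation/matching/evaluation pipeline
#'
#' Generates a synthetic database, scores all pairs with every configured
#' algorithm, evaluates rank CDFs (full database, optional subsampled sizes,
#' optional multi-match values), tabulates the processing-time cost model,
#' and writes everything into a run directory: `manifest.csv`, `pairs.csv`,
#' optional `images/`, `scores_<algorithm>.csv` (resumable checkpoints),
#' `cdf.csv`, `cost.csv` and a plain-text `report.txt`. Every output table
#' carries the config hash for provenance. Re-running an interrupted run
#' resumes from the checkpointed scores.
#'
#' @param config A [run_config()].
#' @param dir Run directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the database, score tables and the CDF
#'   tibble.
#' @export
run_pipeline <- function(config, dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("generating database (seed %d)", config$seed)
  db <- generate_database(config$n_individuals,
                          config$captures_per_individual,
                          config$spec, config$params, config$seed)
  write_database(db, dir, write_images = config$write_images)
  n_images <- nrow(db$captures)
  if (!is.null(config$sizes) && any(config$sizes > n_images)) {
    abort("subsample sizes exceed the database size")
  }

  cdf_rows <- list()
  tables <- list()
  for (alg in config$algorithms) {
    say("scoring all pairs: %s", alg)
    matcher <- resolve_matcher(alg)
    table <- all_pairs_scores(db, matcher,
                              checkpoint = file.path(dir, sprintf("scores_%s.csv", alg)))
    tables[[alg]] <- table
    out_tbl <- dplyr::mutate(as_tibble(table),
                             score = sprintf("%.17g", .data$score),
                             config_hash = hash)
    readr::write_csv(out_tbl, file.path(dir, sprintf("scores_%s.csv", alg)))

    for (k in config$k_values) {
      cdf_full <- multi_match_cdf(db, table, k = k, r_max = config$r_max)
      cdf_rows[[length(cdf_rows) + 1L]] <- tibble(
        algorithm = alg, db_size = n_images, k_matches = k,
        r = cdf_full$r, cdf = cdf_full$cdf, frr = cdf_full$frr,
        n_pairs = attr(cdf_full, "n_pairs"), reps = 1L)
      if (!is.null(config$sizes)) {
        sub <- subsample_cdf(db, table, sizes = config$sizes,
                             reps = config$reps, r_max = config$r_max,
                             seed = config$seed, k = k)
        cdf_rows[[length(cdf_rows) + 1L]] <- tibble(
          algorithm = alg, db_size = sub$db_size, k_matches = k,
          r = sub$r, cdf = sub$cdf, frr = sub$frr,
          n_pairs = sub$n_pairs, reps = sub$reps)
      }
    }
  }
  cdf_tbl <- dplyr::bind_rows(cdf_rows) |>
    dplyr::mutate(config_hash = hash)
  readr::write_csv(cdf_tbl, file.path(dir, "cdf.csv"))

  cost_tbl <- matching_cost(config$cost_sizes) |>
    dplyr::mutate(config_hash = hash)
  readr::write_csv(cost_tbl, file.path(dir, "cost.csv"))

  report <- c(
    sprintf("spotmatch pipeline report (%s)", format(t0)),
    sprintf("package version: %s", as.character(utils::packageVersion("spotmatch"))),
    sprintf("config hash: %s", hash),
    "",
    yaml::as.yaml(list(
      n_individuals = config$n_individuals,
      captures_per_individual = config$captures_per_individual,
      algorithms = config$algorithms, seed = config$seed,
      r_max = config$r_max, sizes = config$sizes,
      k_values = config$k_values)),
    sprintf("images: %d, known pairs: %d", n_images, nrow(db$pairs)),
    sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(report, file.path(dir, "report.txt"))
  say("done: %s", dir)
  invisible(list(db = db, tables = tables, cdf = cdf_tbl, cost = cost_tbl,
                 config_hash = hash))
}
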