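#' Tidy and summarize rank CDF objects
#'
#' `tidy()` returns the per-rank curve as a plain tibble; `glance()` returns
#' a one-row summary with the headline recognition rates `cdf(1)` and
#' `cdf(10)` and the stored metadata.
#'
#' @param x A `rank_cdf`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rank_cdf <- function(x, ...) {
  tibble(r = x$r, cdf = x$cdf, frr = x$frr)
}

#' @rdname tidy.rank_cdf
#' @export
glance.rank_cdf <- function(x, ...) {
  tibble(n_pairs = attr(x, "n_pairs"),
         db_size = attr(x, "db_size"),
         matches_per_query = attr(x, "matches_per_query"),
         replicates = attr(x, "replicates"),
         cdf1 = cdf_at(x, 1),
         cdf10 = if (max(x$r) >= 10) cdf_at(x, 10) else NA_real_)
}

#' @export
tidy.similarity_tbl <- function(x, ...) as_tibble(x)

#' @export
glance.similarity_tbl <- function(x, ...) {
  tibble(algorithm = attr(x, "algorithm"),
         n_images = length(attr(x, "image_ids")),
         n_pairs = nrow(x),
         n_missing = sum(is.na(x$score)))
}

#' @export
print.rank_cdf <- function(x, ...) {
  cat(sprintf("<rank_cdf> %s queries, k = %s, db size %s\n",
              attr(x, "n_pairs"),
              attr(x, "matches_per_query") %||% NA,
              attr(x, "db_size") %||% NA))
  NextMethod()
}

#' Plot a rank cumulative match curve
#'
#' @param object A `rank_cdf` or `subsample_cdf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_cdf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r, y = .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "rank r", y = "cdf(r)",
                  title = "Rank cumulative match curve") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rank_cdf
#' @export
autoplot.subsample_cdf <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$cdf,
                                   colour = factor(.data$db_size))) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "rank r", y = "cdf(r)", colour = "database size",
                  title = "Recognition versus database size") +
    ggplot2::theme_minimal()
}

#' Plot a pattern image
#'
#' @param pattern Intensity matrix.
#' @param title Optional plot title.
#' @return A ggplot object (raster of the pattern, origin top-left).
#' @export
plot_pattern <- function(pattern, title = NULL) {
  m <- to_gray(pattern)
  df <- tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
               col = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
}
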