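#' Read and write pattern images as PNG
#'
#' Patterns are stored as 8-bit grayscale PNG; on read, RGB images are
#' converted with luma weights 0.299/0.587/0.114 and intensities are scaled
#' back to `[0, 255]`.
#'
#' @param path PNG file path.
#' @param pattern Integer/numeric matrix with values in `[0, 255]`.
#' @return `read_pattern()` returns an integer intensity matrix.
#' @export
read_pattern <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- to_gray(img * 255)
  } else {
    img <- img * 255
  }
  as_intensity(img)
}

#' @rdname read_pattern
#' @export
write_pattern <- function(pattern, path) {
  m <- to_gray(pattern)
  png::writePNG(pmin(pmax(m / 255, 0), 1), path)
  invisible(path)
}

#' Write a match database to disk
#'
#' Writes `manifest.csv` (`image_id`, `individual_id`, `capture_index`,
#' `file`), `pairs.csv` (`image_id_a`, `image_id_b`) and, optionally, one
#' grayscale PNG per capture under `images/`.
#'
#' @param db A `match_db`.
#' @param dir Output directory (created if needed).
#' @param write_images Write the PNGs (requires patterns in the database).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir, write_images = TRUE) {
  stopifnot(inherits(db, "match_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  caps <- db$captures
  files <- file.path("images", paste0(caps$image_id, ".png"))
  manifest <- tibble(image_id = caps$image_id,
                     individual_id = caps$individual_id,
                     capture_index = caps$capture_index,
                     file = files)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(db$pairs, file.path(dir, "pairs.csv"))
  if (write_images) {
    if (!"pattern" %in% names(caps)) abort("database carries no patterns")
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    purrr::walk2(caps$pattern, files,
                 function(p, f) write_pattern(p, file.path(dir, f)))
  }
  invisible(dir)
}

#' Read a capture manifest (and optionally its images)
#'
#' Validates the manifest (required columns, unique image ids, contiguous
#' capture indices) and returns a `match_db`; pair ground truth is derived
#' from `individual_id` unless a pairs file is supplied via [read_pairs()].
#'
#' @param path Path to `manifest.csv`.
#' @param load_images If `TRUE`, reads each `file` (relative to the manifest
#'   directory) into a `pattern` list-column.
#' @return A `match_db`.
#' @export
read_manifest <- function(path, load_images = FALSE) {
  man <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("image_id", "individual_id", "capture_index")
  if (!all(need %in% names(man))) {
    abort("manifest must have columns image_id, individual_id, capture_index")
  }
  if (load_images) {
    if (!"file" %in% names(man)) abort("manifest has no `file` column")
    base <- dirname(path)
    man$pattern <- lapply(man$file, function(f) read_pattern(file.path(base, f)))
  }
  match_database(man)
}

#' Read a known-pairs table and attach it to a database
#'
#' @param path Path to `pairs.csv` (`image_id_a`, `image_id_b`).
#' @param db A `match_db` whose manifest the pairs must reference.
#' @return The `match_db` with its pair list replaced.
#' @export
read_pairs <- function(path, db) {
  stopifnot(inherits(db, "match_db"))
  pairs <- readr::read_csv(path, show_col_types = FALSE)
  match_database(db$captures, pairs = pairs, spec = db$spec,
                 params = db$params, seed = db$seed)
}

#' Score table round-trip
#'
#' Scores are written in full precision (round-trip safe) CSV with columns
#' `image_id_a`, `image_id_b`, `score`; extra constant columns (e.g. a
#' provenance hash) are preserved on read.
#'
#' @param table A `similarity_tbl`.
#' @param path CSV path.
#' @param algorithm Algorithm label to attach on read.
#' @return `read_scores()` returns a `similarity_tbl`.
#' @export
write_scores <- function(table, path) {
  tbl <- as_tibble(table)
  # 17 significant digits guarantee an exact double round-trip
  tbl$score <- sprintf("%.17g", tbl$score)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path, algorithm = NA_character_) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(score = readr::col_character()))
  if (!all(c("image_id_a", "image_id_b", "score") %in% names(tbl))) {
    abort("score table must have columns image_id_a, image_id_b, score")
  }
  # base-R strtod conversion round-trips 17-digit decimals exactly
  tbl$score <- as.numeric(tbl$score)
  new_similarity_tbl(tbl, algorithm = algorithm)
}

#' Read a spine polyline from CSV
#'
#' @param path CSV with columns `row`, `col` (1-based image coordinates).
#' @return Two-column numeric matrix usable with [straighten()].
#' @export
read_spine <- function(path) {
  sp <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("row", "col") %in% names(sp))) {
    abort("spine file must have columns row, col")
  }
  as.matrix(sp[, c("row", "col")])
}
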