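# shared internal helpers

# coerce an image to a plain numeric matrix; 3-channel arrays are converted to
# gray with standard luma weights (0.299, 0.587, 0.114)
to_gray <- function(image) {
  if (is.matrix(image)) {
    m <- image
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    d <- dim(image)
    if (d[3] == 1L) {
      m <- image[, , 1L]
    } else {
      w <- c(0.299, 0.587, 0.114)
      m <- image[, , 1L] * w[1] + image[, , 2L] * w[2] + image[, , 3L] * w[3]
      if (d[3] == 4L) m <- m # alpha channel ignored
    }
    storage.mode(m) <- "double"
    return(m)
  }
  abort("`image` must be a matrix or a 3-d array")
}

# store an intensity image as 8-bit-valued integer matrix, keeping attributes
as_intensity <- function(m, foreground = NULL) {
  out <- round(pmin(pmax(m, 0), 255))
  storage.mode(out) <- "integer"
  if (!is.null(foreground)) attr(out, "foreground") <- foreground
  out
}

# derive a fixed number of independent sub-seeds from one master seed
derive_seeds <- function(seed, n) {
  withr::local_seed(seed)
  sample.int(2147483646L, n)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(min), format(max)))
  }
  invisible(x)
}

is_binary_pattern <- function(image) {
  v <- unique(as.vector(image))
  length(v) <= 2L
}
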