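# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_bad(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_bad(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

#' @noRd
gaussian_kernel1d <- function(sigma_px, radius = NULL) {
  if (sigma_px <= 0) return(1)
  radius <- radius %||% max(1L, ceiling(4 * sigma_px))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable 2-D convolution with replicate (edge-extension) padding.
# Kernel is the outer product of a 1-D kernel with itself.
#' @noRd
conv_sep2d <- function(mat, k1d) {
  if (length(k1d) == 1L) return(mat * k1d^2)
  r <- (length(k1d) - 1L) / 2L
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  # rows
  m <- mat[pad_idx(nrow(mat)), , drop = FALSE]
  m <- apply(m, 2L, function(col) stats::filter(col, k1d, sides = 2L))
  m <- m[(r + 1L):(r + nrow(mat)), , drop = FALSE]
  # columns
  m <- m[, pad_idx(ncol(mat)), drop = FALSE]
  m <- t(apply(m, 1L, function(row) stats::filter(row, k1d, sides = 2L)))
  m[, (r + 1L):(r + ncol(mat)), drop = FALSE]
}

# Quantiles everywhere in the package use linear interpolation between order
# statistics (type 7), so q25/q75 are reproducible.
#' @noRd
quantile_lin <- function(x, probs) unname(stats::quantile(x, probs, type = 7, names = FALSE))

# Population standard deviation (divide by n).
#' @noRd
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Run an expression with a temporarily-seeded RNG, restoring global state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
utc_stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
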