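#' Coefficient-of-variance image of a hyper-temporal stack
#'
#' Per pixel, `CV = sigma / |m|`: the population standard deviation (divide
#' by n) over the selected gate frames divided by the absolute mean. High CV
#' flags fast-decaying regions, low CV slow-decaying ones; a water
#' background forms a homogeneous band near CV ~ 0.3 when computed over the
#' diffusion window. Pixels whose |mean| falls below `mean_floor_frac` times
#' the global maximum of the selected frames are masked rather than divided.
#'
#' @param stack A [hyper_stack()].
#' @param window `c(t0, t1)` gate-time range (s) to include. The window is a
#'   required choice: computing over the diffusion window only (gates after
#'   the heating phase) is the recommended convention.
#' @param mean_floor_frac Masking floor as a fraction of the global frame
#'   maximum, default 0.01.
#' @return A `cv_image`: list with `values` (matrix, masked pixels `NA`),
#'   `mask` (logical matrix, `TRUE` = valid), `window`, `convention`
#'   (`"population"`).
#' @export
compute_cv_image <- function(stack, window, mean_floor_frac = 0.01) {
  stopifnot(inherits(stack, "hyper_stack"))
  sel <- which(stack$gate_times >= window[1] - 1e-15 &
               stack$gate_times <= window[2] + 1e-15)
  if (length(sel) < 3L) stop_bad("CV window must select at least 3 frames")
  f <- stack$frames[, , sel, drop = FALSE]
  n <- length(sel)
  m <- apply(f, c(1, 2), mean)
  s <- sqrt(apply(f, c(1, 2), function(x) mean((x - mean(x))^2)))
  floor_abs <- mean_floor_frac * max(abs(f))
  mask <- abs(m) >= floor_abs
  cv <- s / abs(m)
  cv[!mask] <- NA_real_
  structure(list(values = cv, mask = mask, window = window,
                 gate_times = stack$gate_times[sel],
                 convention = "population", mean_floor_frac = mean_floor_frac,
                 pixel_size = stack$pixel_size),
            class = "cv_image")
}

#' @export
print.cv_image <- function(x, ...) {
  cat(sprintf("cv_image: %d x %d px over t_g = %.3g - %.3g s (%d frames, %s sd)\n",
              nrow(x$values), ncol(x$values), x$window[1], x$window[2],
              length(x$gate_times), x$convention))
  cat(sprintf("valid pixels: %d/%d; CV range %.3g - %.3g\n",
              sum(x$mask), length(x$mask),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.cv_image <- function(x, ...) {
  v <- x$values
  graphics::image(t(v[nrow(v):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"), asp = nrow(v) / ncol(v),
                  axes = FALSE, main = "CV image", ...)
  invisible(x)
}

#' Per-pixel 1/e decay-time map
#'
#' Applies [extract_tau()] to every pixel's gate-time series over the given
#' window: the pixel-by-pixel reference that the CV image summarises without
#' fitting. Also records each pixel's CV over the same window so the CV/tau
#' anticorrelation can be assessed directly.
#'
#' @inheritParams compute_cv_image
#' @param floor Passed to [extract_tau()]; `"window"` (default) or a known
#'   numeric floor (0 for synthetic stacks generated with a zero baseline).
#' @return A `tau_map`: list with `tau` (matrix, s; invalid pixels `NA`),
#'   `valid` (logical matrix), `cv` (matrix over the same window when >= 3
#'   frames are selected, else `NULL`), `window`.
#' @export
map_tau <- function(stack, window, floor = "window", mean_floor_frac = 0.01) {
  stopifnot(inherits(stack, "hyper_stack"))
  sel <- which(stack$gate_times >= window[1] - 1e-15 &
               stack$gate_times <= window[2] + 1e-15)
  if (length(sel) < 4L) stop_bad("tau window must select at least 4 frames")
  tt <- stack$gate_times[sel]
  d <- dim(stack$frames)
  tau <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    fit <- tryCatch(extract_tau(stack$frames[y, x, sel], tt, floor = floor),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$valid) { tau[y, x] <- fit$tau_d; valid[y, x] <- TRUE }
  }
  cv <- if (length(sel) >= 3L)
    compute_cv_image(stack, window, mean_floor_frac = mean_floor_frac)$values
  else NULL
  structure(list(tau = tau, valid = valid, cv = cv, window = window,
                 pixel_size = stack$pixel_size),
            class = "tau_map")
}

#' @export
print.tau_map <- function(x, ...) {
  cat(sprintf("tau_map: %d x %d px, window %.3g - %.3g s\n",
              nrow(x$tau), ncol(x$tau), x$window[1], x$window[2]))
  if (any(x$valid))
    cat(sprintf("valid pixels: %d/%d; tau_d range %.3g - %.3g us (median %.3g us)\n",
                sum(x$valid), length(x$valid),
                min(x$tau, na.rm = TRUE) * 1e6, max(x$tau, na.rm = TRUE) * 1e6,
                stats::median(x$tau[x$valid]) * 1e6))
  invisible(x)
}

#' @export
plot.tau_map <- function(x, ...) {
  v <- x$tau * 1e6
  graphics::image(t(v[nrow(v):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "plasma"), asp = nrow(v) / ncol(v),
                  axes = FALSE, main = expression(paste(tau[d], " map (", mu, "s)")), ...)
  invisible(x)
}

#' Linescan container
#'
#' @param positions Positions along the scan (m), strictly increasing.
#' @param values Signal values (mV).
#' @param gate_time Optional gate start time (s) the scan was taken at.
#' @return A `linescan` object.
#' @export
linescan <- function(positions, values, gate_time = NULL) {
  if (length(positions) != length(values) || length(positions) < 3L)
    stop_bad("'positions' and 'values' must be equal-length vectors (>= 3)")
  if (any(diff(positions) <= 0)) stop_bad("'positions' must be strictly increasing")
  structure(list(positions = as.numeric(positions), values = as.numeric(values),
                 gate_time = gate_time),
            class = "linescan")
}

#' Extract a horizontal linescan from a stack frame
#'
#' @param stack A [hyper_stack()].
#' @param y Row index (pixels) of the scan line.
#' @param frame Frame index (or use `gate_time` to select by time).
#' @param gate_time Gate time (s); nearest frame is used.
#' @return A [linescan()].
#' @export
stack_linescan <- function(stack, y, frame = NULL, gate_time = NULL) {
  stopifnot(inherits(stack, "hyper_stack"))
  if (is.null(frame)) {
    if (is.null(gate_time)) stop_bad("supply 'frame' or 'gate_time'")
    frame <- which.min(abs(stack$gate_times - gate_time))
  }
  v <- stack$frames[y, , frame]
  linescan((seq_along(v) - 0.5) * stack$pixel_size, v,
           gate_time = stack$gate_times[frame])
}

#' Full width at half maximum of a linescan peak
#'
#' The half level is referenced to the local baseline, the mean of the two
#' flanking minima (the lowest value on each side of the peak). Crossings
#' are located by linear interpolation; exact-tie plateaus at the half level
#' are resolved toward the wider width.
#'
#' @param scan A [linescan()], or a numeric vector of values (then
#'   `positions` defaults to pixel index).
#' @param positions Positions (m) when `scan` is a bare vector.
#' @return FWHM in the units of `positions`.
#' @export
fwhm_linescan <- function(scan, positions = NULL) {
  if (inherits(scan, "linescan")) { positions <- scan$positions; v <- scan$values }
  else { v <- scan; positions <- positions %||% seq_along(v) }
  n <- length(v)
  ipk <- which.max(v)
  if (ipk == 1L || ipk == n) stop_bad("no interior peak in the linescan")
  left_min <- min(v[1:ipk]); right_min <- min(v[ipk:n])
  base <- (left_min + right_min) / 2
  if (v[ipk] <= base) stop_bad("peak does not rise above its flanking minima")
  half <- base + (v[ipk] - base) / 2

  cross_out <- function(idx_seq) {
    # walk outward from the peak; first strict drop below the half level
    prev <- ipk
    for (j in idx_seq) {
      if (v[j] < half) {
        if (v[prev] == half) return(positions[prev])  # plateau: wider side
        return(positions[prev] + (half - v[prev]) / (v[j] - v[prev]) *
                 (positions[j] - positions[prev]))
      }
      prev <- j
    }
    NA_real_
  }
  xl <- cross_out(rev(seq_len(ipk - 1L)))
  xr <- cross_out(seq(ipk + 1L, n))
  if (is.na(xl) || is.na(xr)) stop_bad("half-maximum level is not crossed on both sides")
  abs(xr - xl)
}

#' Median background subtraction
#'
#' Subtracts the median of the pixels selected by `region_mask` (e.g. the
#' water region) from the whole image, so the masked region's median becomes
#' exactly zero. Idempotent: re-subtracting with the same mask changes
#' nothing.
#'
#' @param image Numeric matrix, or a `cv_image` (its `values` are shifted).
#' @param region_mask Logical matrix selecting the reference region.
#' @return Object of the same type, shifted.
#' @export
background_subtract_median <- function(image, region_mask) {
  vals <- if (inherits(image, "cv_image")) image$values else image
  if (!is.logical(region_mask) || !identical(dim(region_mask), dim(vals)))
    stop_bad("'region_mask' must be a logical matrix matching the image")
  if (!any(region_mask)) stop_bad("'region_mask' selects no pixels")
  med <- stats::median(vals[region_mask], na.rm = TRUE)
  out <- vals - med
  if (inherits(image, "cv_image")) { image$values <- out; image } else out
}

#' Dispersion summary of a value set
#'
#' Reports the shortest interval containing the requested probability mass
#' (default 75%), the convention used for statements like "75% of the water
#' CV values fall between 0.22 and 0.35", plus the central symmetric
#' percentile interval (12.5-87.5% for mass 0.75) as a labelled alternative.
#'
#' @param values Numeric vector (>= 8 values).
#' @param probability_mass Fraction of values the interval must contain,
#'   default 0.75.
#' @return List with `lower`, `upper`, `width` (shortest interval),
#'   `central` (named vector `lower`, `upper`, `width` by symmetric
#'   percentiles) and `probability_mass`.
#' @export
dispersion_summary <- function(values, probability_mass = 0.75) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) stop_bad("need at least 8 finite values")
  if (probability_mass <= 0 || probability_mass > 1)
    stop_bad("'probability_mass' must be in (0, 1]")
  x <- sort(values)
  n <- length(x)
  k <- max(2L, ceiling(probability_mass * n))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- starts[which.min(widths)]
  q <- quantile_lin(x, c((1 - probability_mass) / 2, (1 + probability_mass) / 2))
  list(lower = x[i], upper = x[i + k - 1L], width = x[i + k - 1L] - x[i],
       central = c(lower = q[1], upper = q[2], width = q[2] - q[1]),
       probability_mass = probability_mass)
}
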