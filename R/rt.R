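#' Discrete 2-D Laplacian of a frame
#'
#' Finite-difference Laplacian `(d2/dx2 + d2/dy2)` scaled by
#' `1/pixel_size^2`. The default 5-point stencil is the one used for the
#' rate-of-transfer estimator; a 9-point variant is available for isotropy
#' studies. The border ring, where the stencil is incomplete, is `NA`.
#'
#' @param frame Numeric matrix (>= 3 x 3).
#' @param pixel_size Pixel pitch (m).
#' @param stencil `"five"` (default) or `"nine"`.
#' @return Matrix of Laplacian values (mV/m^2), border `NA`.
#' @export
laplacian2d <- function(frame, pixel_size, stencil = c("five", "nine")) {
  stencil <- match.arg(stencil)
  if (!is.matrix(frame) || nrow(frame) < 3L || ncol(frame) < 3L)
    stop_bad("'frame' must be a matrix of at least 3 x 3")
  check_scalar_pos(pixel_size, "pixel_size")
  ny <- nrow(frame); nx <- ncol(frame)
  out <- matrix(NA_real_, ny, nx)
  ci <- 2:(ny - 1); cj <- 2:(nx - 1)
  C <- frame[ci, cj]
  N <- frame[ci - 1, cj]; S <- frame[ci + 1, cj]
  W <- frame[ci, cj - 1]; E <- frame[ci, cj + 1]
  out[ci, cj] <- if (stencil == "five") {
    (N + S + E + W - 4 * C) / pixel_size^2
  } else {
    NW <- frame[ci - 1, cj - 1]; NE <- frame[ci - 1, cj + 1]
    SW <- frame[ci + 1, cj - 1]; SE <- frame[ci + 1, cj + 1]
    (4 * (N + S + E + W) + NW + NE + SW + SE - 20 * C) / (6 * pixel_size^2)
  }
  out
}

#' Temporal derivative of a stack at a gate time
#'
#' Central difference across the adjacent frames (forward/backward at the
#' ends), divided by the gate-time spacing.
#'
#' @param stack A [hyper_stack()].
#' @param gate_time Gate time (s); the nearest frame is used.
#' @return Matrix of dBC/dt values (mV/s).
#' @export
temporal_derivative <- function(stack, gate_time) {
  stopifnot(inherits(stack, "hyper_stack"))
  nt <- length(stack$gate_times)
  if (nt < 2L) stop_bad("temporal derivative needs at least 2 frames")
  k <- which.min(abs(stack$gate_times - gate_time))
  if (k == 1L) {
    (stack$frames[, , 2] - stack$frames[, , 1]) /
      (stack$gate_times[2] - stack$gate_times[1])
  } else if (k == nt) {
    (stack$frames[, , nt] - stack$frames[, , nt - 1]) /
      (stack$gate_times[nt] - stack$gate_times[nt - 1])
  } else {
    (stack$frames[, , k + 1] - stack$frames[, , k - 1]) /
      (stack$gate_times[k + 1] - stack$gate_times[k - 1])
  }
}

#' Rate-of-transfer estimates
#'
#' In analogy with the thermal diffusion equation, the rate of transfer
#' `RT = (dBC/dt) / laplacian(BC)` (m^2/s) quantifies the local speed
#' toward thermal equilibrium: at a decaying local maximum both the
#' temporal derivative and the Laplacian are negative, so RT is positive,
#' and on an exact heat-kernel field RT equals the thermal diffusivity.
#' Estimates where |laplacian| falls below the adaptive floor (a quantile
#' of the frame's |laplacian|) are flagged invalid rather than divided.
#'
#' @param stack A [hyper_stack()].
#' @param gate_time Gate time (s) within the diffusion window.
#' @param locations `data.frame`/matrix with columns `x_px`, `y_px`, or
#'   `NULL` for all interior pixels.
#' @param lap_floor_quantile Quantile of |laplacian| (interior pixels)
#'   below which estimates are invalid, default 0.8.
#' @param stencil Passed to [laplacian2d()].
#' @param label_map Optional character matrix; adds a `region` column.
#' @return `data.frame` with columns `region` (if given), `gate_time_s`,
#'   `x_px`, `y_px`, `dBC_dt`, `laplacian`, `rt`, `valid`. If no estimate
#'   is valid the set is returned with a warning.
#' @export
compute_rt <- function(stack, gate_time, locations = NULL,
                       lap_floor_quantile = 0.8, stencil = "five",
                       label_map = NULL) {
  stopifnot(inherits(stack, "hyper_stack"))
  k <- which.min(abs(stack$gate_times - gate_time))
  lap <- laplacian2d(stack$frames[, , k], stack$pixel_size, stencil = stencil)
  dbc <- temporal_derivative(stack, gate_time)
  floor_abs <- quantile_lin(abs(lap[is.finite(lap)]), lap_floor_quantile)
  if (is.null(locations)) {
    idx <- which(is.finite(lap), arr.ind = TRUE)
    locations <- data.frame(x_px = idx[, 2], y_px = idx[, 1])
  } else {
    locations <- as.data.frame(locations)
    if (is.null(locations$x_px)) names(locations)[1:2] <- c("x_px", "y_px")
  }
  ii <- cbind(locations$y_px, locations$x_px)
  if (any(ii < 1L) || any(ii[, 1] > nrow(lap)) || any(ii[, 2] > ncol(lap)))
    stop_bad("locations outside the frame")
  l <- lap[ii]; dv <- dbc[ii]
  valid <- is.finite(l) & abs(l) >= floor_abs & abs(l) > 0
  rt <- ifelse(valid, dv / l, NA_real_)
  out <- data.frame(gate_time_s = stack$gate_times[k],
                    x_px = locations$x_px, y_px = locations$y_px,
                    dBC_dt = dv, laplacian = l, rt = rt, valid = valid)
  if (!is.null(label_map)) out <- cbind(region = label_map[ii], out)
  if (!any(valid)) warning("no valid rate-of-transfer estimate at this gate time")
  out
}

#' Locate peaks of the |Laplacian| in a frame
#'
#' Local extrema of `|laplacian|` (strictly greater than all 8 neighbours)
#' above an adaptive quantile threshold, greedily pruned so retained peaks
#' are at least `min_separation` pixels apart, strongest first.
#' Deterministic: ties are ordered by row then column.
#'
#' @param frame_laplacian Matrix from [laplacian2d()] (`NA` border allowed).
#' @param min_separation Minimum Euclidean separation (px), >= 1.
#' @param threshold_quantile Quantile of finite |values| that a peak must
#'   exceed, default 0.8.
#' @return `data.frame` with `x_px`, `y_px`, `value` (of |laplacian|),
#'   ordered strongest first; empty when there is no peak.
#' @export
find_laplacian_peaks <- function(frame_laplacian, min_separation = 3,
                                 threshold_quantile = 0.8) {
  if (min_separation < 1) stop_bad("'min_separation' must be >= 1 px")
  a <- abs(frame_laplacian)
  ny <- nrow(a); nx <- ncol(a)
  thr <- quantile_lin(a[is.finite(a)], threshold_quantile)
  peaks <- NULL
  for (y in 2:(ny - 1)) for (x in 2:(nx - 1)) {
    v <- a[y, x]
    if (!is.finite(v) || v <= thr) next
    nb <- a[(y - 1):(y + 1), (x - 1):(x + 1)]
    nb[2, 2] <- -Inf
    nb <- nb[is.finite(nb)]
    # >= with at least one strict: a ridge of tied values yields candidates
    # along it, thinned afterwards by the separation rule
    if (all(v >= nb) && any(v > nb)) peaks <- rbind(peaks, c(x, y, v))
  }
  if (is.null(peaks)) return(data.frame(x_px = integer(), y_px = integer(),
                                        value = numeric()))
  peaks <- as.data.frame(peaks)
  names(peaks) <- c("x_px", "y_px", "value")
  peaks <- peaks[order(-peaks$value, peaks$y_px, peaks$x_px), , drop = FALSE]
  kept <- peaks[0, ]
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (nrow(kept) == 0L ||
        all(sqrt((kept$x_px - p$x_px)^2 + (kept$y_px - p$y_px)^2) >= min_separation))
      kept <- rbind(kept, p)
  }
  rownames(kept) <- NULL
  kept
}

#' Regional box statistics of rate-of-transfer estimates
#'
#' Mean and 25th/75th percentiles (linear interpolation between order
#' statistics) of valid RT estimates per region - the box-chart summary
#' convention (box = 25-75% margin, middle line = mean).
#'
#' @param estimates `data.frame` of estimates as returned by [compute_rt()]
#'   (pooled over gate times with `rbind` as desired), with a `region`
#'   column.
#' @return A `rt_box_stats` data.frame: `region`, `mean`, `q25`, `q75`,
#'   `n_points`. Regions present but without any valid estimate are omitted
#'   with a warning.
#' @seealso [rt_region_stats()] for the stack-level wrapper that pools the
#'   default five diffusion-window gate times.
#' @export
aggregate_rt <- function(estimates) {
  if (is.null(estimates$region)) stop_bad("'estimates' needs a 'region' column")
  if (is.null(estimates$valid)) estimates$valid <- TRUE
  regions <- sort(unique(as.character(estimates$region)))
  est <- estimates[estimates$valid & is.finite(estimates$rt), , drop = FALSE]
  rows <- lapply(regions, function(r) {
    v <- est$rt[est$region == r]
    if (length(v) == 0L) {
      warning(sprintf("region '%s' has no valid estimate; omitted", r))
      return(NULL)
    }
    data.frame(region = r, mean = mean(v),
               q25 = quantile_lin(v, 0.25), q75 = quantile_lin(v, 0.75),
               n_points = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "gate_times") <- sort(unique(estimates$gate_time_s))
  class(out) <- c("rt_box_stats", class(out))
  out
}

#' Pooled regional RT statistics for a stack
#'
#' Runs [compute_rt()] at each gate time (default five points spanning the
#' 0.75-2 us diffusion window, snapped to the stack's gates) and aggregates
#' the valid estimates per region with [aggregate_rt()].
#'
#' @param stack A [hyper_stack()].
#' @param label_map Character matrix of region tags matching the frames.
#' @param gate_times Gate times (s) to pool, default
#'   `seq(0.75e-6, 2e-6, length.out = 5)`.
#' @param locations Optional locations passed to [compute_rt()] (default
#'   all interior pixels).
#' @param ... Further arguments to [compute_rt()].
#' @return A `rt_box_stats` data.frame (see [aggregate_rt()]).
#' @export
rt_region_stats <- function(stack, label_map, gate_times = NULL,
                            locations = NULL, ...) {
  stopifnot(inherits(stack, "hyper_stack"))
  want <- gate_times %||% seq(0.75e-6, 2e-6, length.out = 5)
  use <- unique(vapply(want, function(g)
    stack$gate_times[which.min(abs(stack$gate_times - g))], numeric(1)))
  est <- do.call(rbind, lapply(use, function(g)
    compute_rt(stack, g, locations = locations, label_map = label_map, ...)))
  aggregate_rt(est)
}

#' @export
print.rt_box_stats <- function(x, ...) {
  cat("rate-of-transfer box statistics (m^2/s), pooled over",
      length(attr(x, "gate_times")), "gate times\n")
  y <- as.data.frame(x)
  y$mean <- sprintf("%.3g", y$mean)
  y$q25 <- sprintf("%.3g", y$q25)
  y$q75 <- sprintf("%.3g", y$q75)
  print(y, row.names = FALSE)
  invisible(x)
}
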