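#' Probe/detection model
#'
#' @param spot_fwhm Probe focal spot FWHM (m), default 1 um. The detected
#'   signal samples the temperature field through a 2-D Gaussian kernel of
#'   this width (no depth sectioning).
#' @param gain Signal (mV) per kelvin of probe-sampled temperature rise.
#' @param noise_std_single Detection noise standard deviation (mV) for a
#'   single pump period. Boxcar averaging over `n_periods` reduces the
#'   effective noise by sqrt(N).
#' @param n_periods Number of averaged periods, default 2040.
#' @return A `probe_model` object.
#' @export
probe_model <- function(spot_fwhm = 1e-6, gain = 1, noise_std_single = 0,
                        n_periods = 2040L) {
  check_scalar_pos(spot_fwhm, "spot_fwhm")
  check_scalar_pos(gain, "gain")
  if (!is.numeric(noise_std_single) || length(noise_std_single) != 1L ||
      noise_std_single < 0)
    stop_bad("'noise_std_single' must be a single non-negative number")
  if (!is.numeric(n_periods) || length(n_periods) != 1L || n_periods < 1)
    stop_bad("'n_periods' must be >= 1")
  structure(list(spot_fwhm = spot_fwhm, gain = gain,
                 noise_std_single = noise_std_single,
                 n_periods = as.integer(n_periods)),
            class = "probe_model")
}

#' Single-location time trace
#'
#' @param times Sample times (s), strictly increasing with uniform spacing
#'   (10 ns by default throughout the package).
#' @param values Signal values (mV).
#' @param location Optional pixel coordinate `c(x, y)`.
#' @param metadata Optional named list.
#' @return A `time_trace` object.
#' @export
time_trace <- function(times, values, location = NULL, metadata = list()) {
  if (length(times) != length(values) || length(times) < 2L)
    stop_bad("'times' and 'values' must be equal-length vectors (>= 2 samples)")
  dt <- diff(times)
  if (any(dt <= 0)) stop_bad("'times' must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop_bad("'times' must be uniformly spaced")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 location = location, metadata = metadata),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("time_trace: %d samples, %.3g - %.3g s (dt = %.3g s), range %.4g - %.4g mV\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$times[2] - x$times[1], min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.time_trace <- function(x, ...) {
  graphics::plot(x$times * 1e6, x$values, type = "l",
                 xlab = expression(paste("time (", mu, "s)")),
                 ylab = "signal (mV)", ...)
  invisible(x)
}

#' @noRd
probe_kernel1d <- function(probe, pixel_size) {
  gaussian_kernel1d(probe$spot_fwhm / (2 * sqrt(2 * log(2))) / pixel_size)
}

#' Convert a temperature movie into a detector time trace
#'
#' The probe samples the temperature field through a 2-D Gaussian kernel of
#' the probe spot FWHM centred on `location`; the trace value is
#' `gain * (kernel-weighted mean temperature rise)` interpolated linearly in
#' time to a uniform 10 ns grid.
#'
#' @param movie A `temperature_movie` from [simulate_temperature_field()].
#' @param probe A [probe_model()].
#' @param location Pixel coordinate `c(x, y)` (column, row), 1-based.
#' @param times Requested trace times (s); default a 10 ns grid spanning the
#'   movie. Must lie within the movie's frame times.
#' @return A [time_trace()] in mV.
#' @export
movie_to_trace <- function(movie, probe, location, times = NULL) {
  stopifnot(inherits(movie, "temperature_movie"), inherits(probe, "probe_model"))
  d <- dim(movie$frames)
  x <- as.integer(location[1]); y <- as.integer(location[2])
  if (is.na(x) || is.na(y) || x < 1L || x > d[2] || y < 1L || y > d[1])
    stop_bad("'location' lies outside the field")
  times <- times %||% seq(movie$times[1], movie$times[length(movie$times)], by = 1e-8)
  if (min(times) < movie$times[1] - 1e-15 || max(times) > movie$times[length(movie$times)] + 1e-15)
    stop_bad("requested trace times are not covered by the movie")

  k1 <- probe_kernel1d(probe, movie$phantom$pixel_size)
  r <- (length(k1) - 1L) / 2L
  # replicate-padded neighbourhood, weighted by the separable kernel
  yi <- pmin(pmax(y + seq(-r, r), 1L), d[1])
  xi <- pmin(pmax(x + seq(-r, r), 1L), d[2])
  w <- outer(k1, k1)
  raw <- vapply(seq_len(d[3]), function(i) sum(w * movie$frames[yi, xi, i]), numeric(1))
  vals <- stats::approx(movie$times, raw, xout = times)$y
  time_trace(times, probe$gain * vals, location = c(x = x, y = y),
             metadata = list(spot_fwhm = probe$spot_fwhm, gain = probe$gain))
}

#' Boxcar gating configuration
#'
#' Windows are half-open `[start, start + width)` on sample timestamps, so
#' gating is bit-reproducible. The baseline window defaults to `NULL`,
#' meaning a zero reference: simulated traces have an exactly zero pre-pulse
#' baseline. On instrument-style traces spanning a full period, set it to a
#' signal-free interval (e.g. the last 1 us of the 10 us period,
#' `c(9e-6, 1e-6)`).
#'
#' @param gate_start Gate start time t_g (s).
#' @param gate_width Gate width (s), default 250 ns (half the pump pulse).
#' @param baseline_window `c(start, width)` in s, or `NULL` for a zero
#'   baseline.
#' @param take_absolute Use the absolute value of the boxcar output
#'   (default `TRUE`, the convention for image reconstruction).
#' @return A `boxcar_config` object.
#' @export
boxcar_config <- function(gate_start, gate_width = 250e-9,
                          baseline_window = NULL, take_absolute = TRUE) {
  if (!is.numeric(gate_start) || length(gate_start) != 1L || gate_start < 0)
    stop_bad("'gate_start' must be a single non-negative time")
  check_scalar_pos(gate_width, "gate_width")
  check_flag(take_absolute, "take_absolute")
  if (!is.null(baseline_window)) {
    if (length(baseline_window) != 2L || baseline_window[2] <= 0)
      stop_bad("'baseline_window' must be c(start, width) with width > 0")
    b0 <- baseline_window[1]; b1 <- baseline_window[1] + baseline_window[2]
    if (b0 < gate_start + gate_width && gate_start < b1)
      stop_bad("gate and baseline windows must not overlap")
  }
  structure(list(gate_start = gate_start, gate_width = gate_width,
                 baseline_window = baseline_window,
                 take_absolute = take_absolute),
            class = "boxcar_config")
}

#' @noRd
window_index <- function(times, start, width) {
  which(times >= start - 1e-15 & times < start + width - 1e-15)
}

#' Boxcar output for one trace
#'
#' `BC = |mean over the gate window - mean over the baseline window|`, the
#' absolute value applied only when `take_absolute` is on. Averages use all
#' samples whose timestamps fall in the half-open window
#' `[start, start + width)`.
#'
#' @param trace A [time_trace()].
#' @param cfg A [boxcar_config()].
#' @return Boxcar value (mV).
#' @export
gate_signal <- function(trace, cfg) {
  stopifnot(inherits(trace, "time_trace"), inherits(cfg, "boxcar_config"))
  tt <- trace$times
  dt <- tt[2] - tt[1]
  if (cfg$gate_start < tt[1] - 1e-15 ||
      cfg$gate_start + cfg$gate_width > tt[length(tt)] + dt + 1e-15)
    stop_bad("gate window lies outside the trace support")
  gi <- window_index(tt, cfg$gate_start, cfg$gate_width)
  if (length(gi) == 0L) stop_bad("gate window contains no samples after discretisation")
  bc <- mean(trace$values[gi])
  if (!is.null(cfg$baseline_window)) {
    b <- cfg$baseline_window
    if (b[1] < tt[1] - 1e-15 || b[1] + b[2] > tt[length(tt)] + dt + 1e-15)
      stop_bad("baseline window lies outside the trace support")
    bi <- window_index(tt, b[1], b[2])
    if (length(bi) == 0L) stop_bad("baseline window contains no samples after discretisation")
    bc <- bc - mean(trace$values[bi])
  }
  if (cfg$take_absolute) abs(bc) else bc
}

#' Hyper-temporal boxcar stack
#'
#' An ordered sequence of 2-D boxcar frames, one per gate start time: the
#' central analysis object. Constructed directly, by [build_stack()], or
#' read from disk with [read_stack()].
#'
#' @param frames Array `y * x * n_frames` (mV).
#' @param gate_times Gate start times (s), strictly increasing, one per
#'   frame.
#' @param pixel_size Pixel pitch (m).
#' @param gate_width Gate width (s).
#' @param metadata Named list (provenance: seed, config hash, ...).
#' @return A `hyper_stack` object.
#' @export
hyper_stack <- function(frames, gate_times, pixel_size, gate_width = 250e-9,
                        metadata = list()) {
  if (length(dim(frames)) != 3L) stop_bad("'frames' must be a 3-D array (y, x, frame)")
  if (dim(frames)[3] != length(gate_times))
    stop_bad("one gate time per frame is required")
  if (length(gate_times) > 1L && any(diff(gate_times) <= 0))
    stop_bad("'gate_times' must be strictly increasing")
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(gate_width, "gate_width")
  structure(list(frames = frames, gate_times = as.numeric(gate_times),
                 pixel_size = pixel_size, gate_width = gate_width,
                 metadata = metadata),
            class = "hyper_stack")
}

#' @export
print.hyper_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("hyper_stack: %d frames of %d x %d px, t_g = %.3g - %.3g s (gate %.3g s)\n",
              d[3], d[1], d[2], x$gate_times[1], x$gate_times[d[3]], x$gate_width))
  cat(sprintf("pixel size %.0f nm; BC range %.4g - %.4g mV\n",
              x$pixel_size * 1e9, min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
plot.hyper_stack <- function(x, frame = 1L, ...) {
  f <- x$frames[, , frame]
  ext_x <- ncol(f) * x$pixel_size * 1e6
  ext_y <- nrow(f) * x$pixel_size * 1e6
  graphics::image(seq(0, ext_x, length.out = ncol(f)),
                  seq(0, ext_y, length.out = nrow(f)),
                  t(f[nrow(f):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "inferno"), asp = 1,
                  xlab = expression(paste("x (", mu, "m)")),
                  ylab = expression(paste("y (", mu, "m)")),
                  main = sprintf("BC, t_g = %.2f us", x$gate_times[frame] * 1e6), ...)
  invisible(x)
}

#' Assemble a hyper-temporal stack from a temperature movie
#'
#' Convolves each movie frame with the probe kernel, interpolates every
#' pixel's trace to a uniform 10 ns grid and applies the boxcar gate at each
#' requested gate start time. Each pixel of each output frame equals
#' [gate_signal()] applied to that pixel's [movie_to_trace()] trace.
#'
#' @param movie A `temperature_movie`.
#' @param probe A [probe_model()].
#' @param gate_times Gate start times (s); the default reproduces the
#'   canonical 0-2 us sweep in 250 ns steps (9 frames).
#' @param cfg A [boxcar_config()]; its `gate_start` is ignored in favour of
#'   `gate_times`.
#' @return A [hyper_stack()].
#' @export
build_stack <- function(movie, probe, gate_times = seq(0, 2e-6, by = 250e-9),
                        cfg = boxcar_config(0)) {
  stopifnot(inherits(movie, "temperature_movie"), inherits(probe, "probe_model"),
            inherits(cfg, "boxcar_config"))
  d <- dim(movie$frames)
  k1 <- probe_kernel1d(probe, movie$phantom$pixel_size)
  conv <- array(0, d)
  for (i in seq_len(d[3])) conv[, , i] <- conv_sep2d(movie$frames[, , i], k1)

  tmin <- movie$times[1]; tmax <- movie$times[length(movie$times)]
  tt <- seq(tmin, tmax, by = 1e-8)
  dt <- 1e-8
  windows <- c(list(gate = NULL), if (!is.null(cfg$baseline_window)) list(baseline = NULL))
  gate_mean <- function(start, width) {
    if (start < tt[1] - 1e-15 || start + width > tt[length(tt)] + dt + 1e-15)
      stop_bad("gate window lies outside the trace support")
    idx <- window_index(tt, start, width)
    if (length(idx) == 0L) stop_bad("gate window contains no samples after discretisation")
    acc <- matrix(0, d[1], d[2])
    for (i in idx) {
      ti <- tt[i]
      k <- findInterval(ti, movie$times, rightmost.closed = TRUE)
      k <- min(max(k, 1L), d[3] - 1L)
      w2 <- (ti - movie$times[k]) / (movie$times[k + 1] - movie$times[k])
      acc <- acc + (1 - w2) * conv[, , k] + w2 * conv[, , k + 1]
    }
    acc / length(idx)
  }
  base <- if (!is.null(cfg$baseline_window))
    gate_mean(cfg$baseline_window[1], cfg$baseline_window[2]) else 0
  frames <- array(NA_real_, c(d[1], d[2], length(gate_times)))
  for (g in seq_along(gate_times)) {
    bc <- probe$gain * (gate_mean(gate_times[g], cfg$gate_width) - base)
    frames[, , g] <- if (cfg$take_absolute) abs(bc) else bc
  }
  hyper_stack(frames, gate_times, movie$phantom$pixel_size, cfg$gate_width,
              metadata = list(gain = probe$gain, spot_fwhm = probe$spot_fwhm,
                              take_absolute = cfg$take_absolute))
}

#' Stack acquisition with a co-scanned Gaussian pump
#'
#' Physically faithful scanning model for small phantoms: for every pixel
#' the pump Gaussian is re-centred on that pixel, the heat equation is
#' re-solved, and the probe trace at the same pixel is gated. O(pixels)
#' simulations - use on small grids.
#'
#' @inheritParams build_stack
#' @param phantom,pulse,config Simulation inputs; `config$pump_mode` must be
#'   `"co_scanned"`.
#' @return A [hyper_stack()].
#' @export
build_stack_co_scanned <- function(phantom, pulse, config, probe,
                                   gate_times = seq(0, 2e-6, by = 250e-9),
                                   cfg = boxcar_config(0)) {
  if (config$pump_mode != "co_scanned")
    stop_bad("build_stack_co_scanned requires pump_mode 'co_scanned'")
  d <- dim(phantom$absorption_map)
  frames <- array(NA_real_, c(d[1], d[2], length(gate_times)))
  dx <- phantom$pixel_size
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    ctr <- c((x - 0.5) * dx, (y - 0.5) * dx)
    movie <- simulate_temperature_field(phantom, pulse, config, pump_center = ctr)
    tr <- movie_to_trace(movie, probe, c(x, y))
    for (g in seq_along(gate_times)) {
      cfg_g <- cfg; cfg_g$gate_start <- gate_times[g]
      frames[y, x, g] <- gate_signal(tr, cfg_g)
    }
  }
  hyper_stack(frames, gate_times, dx, cfg$gate_width,
              metadata = list(pump_mode = "co_scanned"))
}

#' Add period-averaged detection noise
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `noise_std_single / sqrt(n_periods)`: statistically identical to
#' averaging `n_periods` raw periods, at a fraction of the cost.
#' Deterministic for a fixed seed; the global RNG state is restored.
#'
#' @param x A [time_trace()] or [hyper_stack()].
#' @param probe A [probe_model()] carrying the noise parameters.
#' @param seed Integer seed.
#' @return Object of the same class with noise added.
#' @export
add_noise <- function(x, probe, seed = 1L) {
  stopifnot(inherits(probe, "probe_model"))
  sd_eff <- probe$noise_std_single / sqrt(probe$n_periods)
  if (sd_eff == 0) return(x)
  if (inherits(x, "time_trace")) {
    x$values <- x$values + with_seed(seed, stats::rnorm(length(x$values), 0, sd_eff))
  } else if (inherits(x, "hyper_stack")) {
    x$frames <- x$frames + with_seed(seed, array(stats::rnorm(length(x$frames), 0, sd_eff),
                                                 dim(x$frames)))
    x$metadata$noise_seed <- as.integer(seed)
  } else stop_bad("'x' must be a time_trace or hyper_stack")
  x
}

#' First-harmonic lock-in demodulation
#'
#' Amplitude and phase of the first Fourier component at the given
#' frequency. Calibration is peak (not RMS): a pure `A * sin(2 pi f t)`
#' input returns amplitude `A` and phase 0.
#'
#' @param trace A [time_trace()] spanning an integer number of periods of
#'   `frequency`.
#' @param frequency Demodulation frequency (Hz), default 100 kHz.
#' @return List with `amplitude` (mV) and `phase` (rad).
#' @export
lockin_demodulate <- function(trace, frequency = 1e5) {
  stopifnot(inherits(trace, "time_trace"))
  check_scalar_pos(frequency, "frequency")
  tt <- trace$times
  dt <- tt[2] - tt[1]
  span <- tt[length(tt)] - tt[1] + dt   # trace covers n full sample bins
  ncyc <- span * frequency
  if (abs(ncyc - round(ncyc)) > 1e-6 || round(ncyc) < 1)
    stop_bad("trace must span an integer number of demodulation periods")
  ph <- 2 * pi * frequency * tt
  a <- 2 * mean(trace$values * sin(ph))
  b <- 2 * mean(trace$values * cos(ph))
  list(amplitude = sqrt(a^2 + b^2), phase = atan2(b, a))
}

#' Signal-to-noise ratio of a linescan
#'
#' `SNR = (max over the signal region - mean over the noise region) /
#' (sd over the noise region)` (sample standard deviation).
#'
#' @param values Linescan values (mV).
#' @param signal_region,noise_region Index vectors into `values`.
#' @return SNR (dimensionless).
#' @export
snr_linescan <- function(values, signal_region, noise_region) {
  if (length(noise_region) < 8L) stop_bad("noise region must contain >= 8 samples")
  nv <- values[noise_region]
  s <- stats::sd(nv)
  if (s == 0) stop_bad("noise region has zero standard deviation; SNR undefined")
  (max(values[signal_region]) - mean(nv)) / s
}
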