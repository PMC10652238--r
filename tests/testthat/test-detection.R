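zero_movie <- function(n = 21, nf = 11, total = 2e-6) {
  ph <- thermal_phantom(matrix(1e-3, n, n), matrix(1.4e-7, n, n),
                        matrix(4.18e6, n, n), matrix("water", n, n),
                        pixel_size = 200e-9)
  structure(list(frames = array(0, c(n, n, nf)),
                 times = seq(0, total, length.out = nf), phantom = ph),
            class = "temperature_movie")
}

test_that("probe sampling maps temperature movies to traces correctly", {
  mv <- zero_movie()
  pr <- probe_model(gain = 2.5)
  # zero field -> zero trace
  tr <- movie_to_trace(mv, pr, c(10, 10))
  expect_equal(max(abs(tr$values)), 0)
  expect_equal(tr$times[2] - tr$times[1], 1e-8)
  # spatially uniform field -> gain * f(t), independent of spot size
  f <- exp(-mv$times / 1.5e-6)
  mv$frames <- array(rep(f, each = 21 * 21), c(21, 21, 11))
  tr2 <- movie_to_trace(mv, pr, c(10, 10))
  expect_equal(tr2$values, 2.5 * approx(mv$times, f, tr2$times)$y, tolerance = 1e-12)
  tr3 <- movie_to_trace(mv, probe_model(gain = 2.5, spot_fwhm = 3e-6), c(10, 10))
  expect_equal(tr2$values, tr3$values, tolerance = 1e-12)
  expect_error(movie_to_trace(mv, pr, c(50, 10)), "outside")
})

test_that("a point-like hot pixel is weighted by the kernel centre", {
  mv <- zero_movie(nf = 3, total = 1e-6)
  mv$frames[11, 11, ] <- 7          # constant-in-time hot pixel
  pr <- probe_model(gain = 3, spot_fwhm = 1e-6)
  tr <- movie_to_trace(mv, pr, c(11, 11))
  # independent oracle: explicit discrete 2-D Gaussian weights
  sig <- 1e-6 / (2 * sqrt(2 * log(2))) / 200e-9
  rad <- ceiling(4 * sig)
  g <- exp(-(-rad:rad)^2 / (2 * sig^2)); g <- g / sum(g)
  expect_equal(unique(round(tr$values, 12)), round(3 * 7 * g[rad + 1]^2, 12))
})

test_that("boxcar gating implements half-open windows with baseline subtraction", {
  tt <- seq(0, 10e-6, by = 1e-8)
  # constant trace with equal baseline cancels
  tr <- time_trace(tt, rep(4.2, length(tt)))
  cfg <- boxcar_config(0.5e-6, 250e-9, baseline_window = c(9e-6, 1e-6))
  expect_equal(gate_signal(tr, cfg), 0)
  # gate mean 3, baseline mean 0.5 -> 2.5
  v <- rep(0.5, length(tt))
  v[tt >= 0.5e-6 & tt < 0.75e-6] <- 3
  expect_equal(gate_signal(time_trace(tt, v), cfg), 2.5)
  # sign convention: absolute value only when requested
  cfg_s <- boxcar_config(0.5e-6, 250e-9, baseline_window = c(9e-6, 1e-6),
                         take_absolute = FALSE)
  expect_equal(gate_signal(time_trace(tt, 1 - v), cfg_s), -2.5)
  expect_equal(gate_signal(time_trace(tt, 1 - v), cfg), 2.5)
  # windows must not overlap and must lie inside the support
  expect_error(boxcar_config(0.5e-6, 250e-9, baseline_window = c(0.6e-6, 1e-6)),
               "overlap")
  expect_error(gate_signal(tr, boxcar_config(9.9e-6, 250e-9)), "support")
})

test_that("gated exponential matches the analytic window average", {
  tau <- 1.5e-6
  tt <- seq(0, 5e-6, by = 1e-8)
  tr <- exp_decay_trace(tau, times = tt)
  bc <- gate_signal(tr, boxcar_config(0.75e-6, 250e-9))
  # analytic mean of exp(-t/tau) over [0.75, 1.0] us (quadrature oracle)
  exact <- tau / 250e-9 * (exp(-0.75e-6 / tau) - exp(-1e-6 / tau))
  quad <- integrate(function(t) exp(-t / tau), 0.75e-6, 1e-6)$value / 250e-9
  expect_equal(exact, quad, tolerance = 1e-9)
  # discrete left-Riemann average over 25 samples vs integral: first-order gap
  expect_equal(bc, exact, tolerance = 5e-3)
})

test_that("stacks have one frame per gate time and agree with per-pixel gating", {
  m <- mats0()
  ph <- build_interface_phantom(field_size = c(8e-6, 8e-6), pixel_size = 250e-9,
                                interface_position = 4e-6,
                                side_a_props = m$axon_bundle, side_b_props = m$water)
  mv <- simulate_temperature_field(ph, pump_pulse(), sim_config(total_time = 2.5e-6))
  pr <- probe_model()
  gates <- seq(0, 2e-6, by = 250e-9)
  st <- build_stack(mv, pr, gate_times = gates)
  expect_equal(dim(st$frames)[3], 9L)   # 0-2 us in 250 ns steps
  expect_equal(st$gate_times, gates)
  # single gate time reproduces the per-pixel gate_signal map
  st1 <- build_stack(mv, pr, gate_times = 0.75e-6)
  for (px in list(c(5, 5), c(16, 20), c(28, 9))) {
    tr <- movie_to_trace(mv, pr, px)
    expect_equal(st1$frames[px[2], px[1], 1],
                 gate_signal(tr, boxcar_config(0.75e-6)), tolerance = 1e-10)
  }
  # uniform movie -> spatially constant frames
  mvu <- zero_movie()
  mvu$frames <- array(rep(exp(-mvu$times / 1e-6), each = 21 * 21), c(21, 21, 11))
  stu <- build_stack(mvu, pr, gate_times = c(0.5e-6, 1e-6))
  expect_equal(apply(stu$frames, 3, function(f) diff(range(f))), c(0, 0),
               tolerance = 1e-13)
})

test_that("noise injection follows the period-averaged sqrt(N) law deterministically", {
  tt <- seq(0, 10e-6, by = 1e-7)
  tr <- time_trace(tt, rep(0, length(tt)))
  # zero noise amplitude is the identity
  expect_identical(add_noise(tr, probe_model(noise_std_single = 0), 1), tr)
  # determinism
  pr <- probe_model(noise_std_single = 0.5, n_periods = 4)
  expect_identical(add_noise(tr, pr, 7)$values, add_noise(tr, pr, 7)$values)
  # sqrt(N): N = 4 halves the std relative to N = 1, within 5% at 1e5 draws
  big <- time_trace(seq_len(1e5) * 1e-8, rep(0, 1e5))
  s4 <- sd(add_noise(big, probe_model(noise_std_single = 1, n_periods = 4), 11)$values)
  s1 <- sd(add_noise(big, probe_model(noise_std_single = 1, n_periods = 1), 12)$values)
  expect_equal(s4 / s1, 0.5, tolerance = 0.05)
})

test_that("lock-in demodulation uses the peak-amplitude sine convention", {
  f <- 1e5
  tt <- seq(0, 2e-5 - 1e-8, by = 1e-8)  # exactly two periods
  out <- lockin_demodulate(time_trace(tt, 2.3 * sin(2 * pi * f * tt)), f)
  expect_equal(out$amplitude, 2.3, tolerance = 1e-9)
  expect_equal(out$phase, 0, tolerance = 1e-9)
  # DC has no fundamental component
  expect_lt(lockin_demodulate(time_trace(tt, rep(5, length(tt))), f)$amplitude, 1e-9)
  # pulse + decay vs direct numerical Fourier integral (quadrature oracle)
  wave <- function(t) {
    t <- t %% 1e-5
    ifelse(t < 5e-7, t / 5e-7, exp(-(t - 5e-7) / 1e-6))
  }
  out2 <- lockin_demodulate(time_trace(tt, wave(tt)), f)
  a_ref <- 2 * integrate(function(t) wave(t) * sin(2 * pi * f * t), 0, 1e-5,
                         subdivisions = 2000)$value / 1e-5
  b_ref <- 2 * integrate(function(t) wave(t) * cos(2 * pi * f * t), 0, 1e-5,
                         subdivisions = 2000)$value / 1e-5
  expect_equal(out2$amplitude, sqrt(a_ref^2 + b_ref^2), tolerance = 1e-3)
  expect_equal(out2$phase, atan2(b_ref, a_ref), tolerance = 1e-3)
  # non-integer period coverage is rejected
  expect_error(lockin_demodulate(time_trace(tt[1:1500], sin(2 * pi * f * tt[1:1500])), f),
               "integer number")
})

test_that("linescan SNR is scale invariant and follows sqrt(N) averaging", {
  x <- seq(-5, 5, by = 0.1)
  bump <- 10 * exp(-x^2 / 0.5)
  noise_idx <- which(abs(x) > 3)
  vals <- bump
  vals[noise_idx] <- vals[noise_idx] + rep(c(-1, 1), length.out = length(noise_idx))
  snr <- snr_linescan(vals, which(abs(x) < 1), noise_idx)
  expect_equal(snr, snr_linescan(3.7 * vals, which(abs(x) < 1), noise_idx))
  expect_error(snr_linescan(rep(1, 50), 1:3, 10:20), "zero standard deviation")
  expect_error(snr_linescan(vals, 1:3, 1:4), ">= 8")

  # bead linescan: quadrupling the averaged periods doubles the SNR
  ratios <- vapply(1:10, function(seed) {
    noisy <- function(n_periods, s) {
      tr <- time_trace(seq_along(x) * 1e-8, bump)
      add_noise(tr, probe_model(noise_std_single = 1, n_periods = n_periods), s)$values
    }
    s2040 <- snr_linescan(noisy(2040, seed), which(abs(x) < 1), noise_idx)
    s510 <- snr_linescan(noisy(510, seed + 100), which(abs(x) < 1), noise_idx)
    s2040 / s510
  }, numeric(1))
  expect_equal(median(ratios), 2, tolerance = 0.1)
})

test_that("peak-gated boxcar beats the whole-trace mean for pulsed decays", {
  # readout-noise model: both estimators produce one number per pixel with
  # the same noise floor, so the SNR ordering reduces to the signal ordering
  tt <- seq(0, 10e-6, by = 1e-8)
  for (tau in c(0.5e-6, 1e-6, 1.9e-6)) {
    v <- ifelse(tt < 5e-7, tt / 5e-7, exp(-(tt - 5e-7) / tau))
    tr <- time_trace(tt, v)
    bc <- gate_signal(tr, boxcar_config(0.5e-6, 250e-9))
    expect_gt(bc, mean(v))
  }
})
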