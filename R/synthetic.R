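#' Synthetic exponential-decay boxcar trace
#'
#' Generates `BC(t) = amplitude * exp(-t/tau) + baseline` on a uniform
#' grid: the canonical noiseless single-location transient used for
#' parameter-recovery studies.
#'
#' @param tau Decay constant (s).
#' @param times Sample times (s), default 0-5 us at 10 ns.
#' @param amplitude Peak amplitude (mV), default 1.
#' @param baseline Additive baseline (mV), default 0.
#' @return A [time_trace()].
#' @export
exp_decay_trace <- function(tau, times = seq(0, 5e-6, by = 1e-8),
                            amplitude = 1, baseline = 0) {
  check_scalar_pos(tau, "tau")
  time_trace(times, amplitude * exp(-times / tau) + baseline,
             metadata = list(tau = tau, baseline = baseline))
}

#' Synthetic double-exponential boxcar trace
#'
#' `BC(t) = a_fast * exp(-t/tau_fast) + a_slow * exp(-t/tau_slow) +
#' baseline`: the transient shape observed at an interface backed by small
#' features, where a fast feature-sized decay is followed by slower supply
#' from the warmer surroundings.
#'
#' @param tau_fast,tau_slow Decay constants (s), `tau_fast < tau_slow`.
#' @param times Sample times (s), default 0-5 us at 10 ns.
#' @param a_fast,a_slow Component amplitudes (mV), default equal (1, 1).
#' @param baseline Additive baseline (mV), default 0.
#' @return A [time_trace()].
#' @export
double_exp_trace <- function(tau_fast, tau_slow, times = seq(0, 5e-6, by = 1e-8),
                             a_fast = 1, a_slow = 1, baseline = 0) {
  check_scalar_pos(tau_fast, "tau_fast"); check_scalar_pos(tau_slow, "tau_slow")
  if (tau_fast >= tau_slow) stop_bad("'tau_fast' must be smaller than 'tau_slow'")
  time_trace(times,
             a_fast * exp(-times / tau_fast) + a_slow * exp(-times / tau_slow) + baseline,
             metadata = list(tau_fast = tau_fast, tau_slow = tau_slow))
}

#' Synthetic exponential-decay hyper-stack
#'
#' Builds a noiseless stack whose pixel (y, x) follows
#' `amplitude(y, x) * exp(-t_g / tau(y, x))` at the given gate times: the
#' idealised image of a sample whose every location decays single-
#' exponentially, used to validate CV and tau mapping.
#'
#' @param tau_map Matrix of decay constants (s).
#' @param gate_times Gate start times (s), default the 0-2 us sweep in
#'   250 ns steps.
#' @param amplitude Scalar or matrix of peak amplitudes (mV), default 1.
#' @param pixel_size Pixel pitch (m), default 200 nm.
#' @param gate_width Gate width (s), default 250 ns.
#' @return A [hyper_stack()].
#' @export
exponential_stack <- function(tau_map, gate_times = seq(0, 2e-6, by = 250e-9),
                              amplitude = 1, pixel_size = 200e-9,
                              gate_width = 250e-9) {
  if (!is.matrix(tau_map) || any(tau_map <= 0))
    stop_bad("'tau_map' must be a matrix of positive decay constants")
  if (is.matrix(amplitude) && !identical(dim(amplitude), dim(tau_map)))
    stop_bad("'amplitude' matrix must match 'tau_map'")
  frames <- array(NA_real_, c(nrow(tau_map), ncol(tau_map), length(gate_times)))
  for (g in seq_along(gate_times))
    frames[, , g] <- amplitude * exp(-gate_times[g] / tau_map)
  hyper_stack(frames, gate_times, pixel_size, gate_width,
              metadata = list(generator = "exponential_stack"))
}

#' Analytic 2-D heat-kernel stack
#'
#' Frames follow the exact free-space solution of the 2-D heat equation for
#' a Gaussian initial condition: `T(r, t) = (s0^2 / s^2(t)) *
#' exp(-r^2 / (2 s^2(t)))` with `s^2(t) = s0^2 + 2 alpha t`. The identity
#' `dT/dt = alpha * laplacian(T)` makes this the independent oracle for the
#' rate-of-transfer estimator: RT recovered anywhere on this stack equals
#' `alpha`.
#'
#' @param alpha Thermal diffusivity (m^2/s).
#' @param sigma0 Initial Gaussian width (m).
#' @param grid_size Pixels per side.
#' @param pixel_size Pixel pitch (m).
#' @param gate_times Frame times (s) measured from the initial condition.
#' @return A [hyper_stack()] (centre of the Gaussian at the grid centre).
#' @export
heat_kernel_stack <- function(alpha, sigma0, grid_size = 101L,
                              pixel_size = 100e-9,
                              gate_times = seq(0.75e-6, 2e-6, by = 250e-9)) {
  check_scalar_pos(alpha, "alpha"); check_scalar_pos(sigma0, "sigma0")
  ctr <- (grid_size + 1) / 2
  xy <- (seq_len(grid_size) - ctr) * pixel_size
  r2 <- outer(xy^2, xy^2, `+`)
  frames <- array(NA_real_, c(grid_size, grid_size, length(gate_times)))
  for (g in seq_along(gate_times)) {
    s2 <- sigma0^2 + 2 * alpha * gate_times[g]
    frames[, , g] <- sigma0^2 / s2 * exp(-r2 / (2 * s2))
  }
  hyper_stack(frames, gate_times, pixel_size,
              metadata = list(generator = "heat_kernel_stack", alpha = alpha))
}
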