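test_that("Laplacian stencil matches closed forms and a brute-force oracle", {
  dx <- 1e-6
  n <- 9
  xi <- matrix(rep(1:n, each = n), n, n)          # column index = x
  yi <- matrix(rep(1:n, times = n), n, n)
  # linear ramp: zero Laplacian in the interior
  lin <- laplacian2d(3 * xi + 2 * yi, dx)
  expect_equal(max(abs(lin[2:8, 2:8])), 0)
  expect_true(all(is.na(lin[1, ])))
  # quadratic a*x^2 (x in metres): Laplacian 2a
  a <- 4e11
  quad <- laplacian2d(a * (xi * dx)^2, dx)
  expect_equal(as.vector(quad[2:8, 2:8]), rep(2 * a, 49), tolerance = 1e-10)
  # arbitrary integer frame vs direct stencil evaluation
  set.seed(3)
  f <- matrix(sample(-20:20, 25, replace = TRUE), 5, 5)
  lap <- laplacian2d(f, dx)
  for (i in 2:4) for (j in 2:4) {
    ref <- (f[i - 1, j] + f[i + 1, j] + f[i, j - 1] + f[i, j + 1] - 4 * f[i, j]) / dx^2
    expect_equal(lap[i, j], ref)
  }
  lap9 <- laplacian2d(f, dx, stencil = "nine")
  for (i in 2:4) for (j in 2:4) {
    ref <- (4 * (f[i - 1, j] + f[i + 1, j] + f[i, j - 1] + f[i, j + 1]) +
            f[i - 1, j - 1] + f[i - 1, j + 1] + f[i + 1, j - 1] + f[i + 1, j + 1] -
            20 * f[i, j]) / (6 * dx^2)
    expect_equal(lap9[i, j], ref)
  }
  expect_error(laplacian2d(matrix(1, 2, 2), dx), "3 x 3")
})

test_that("temporal derivative is exact on linear stacks and bounded on exponentials", {
  gates <- seq(0.5e-6, 2e-6, by = 250e-9)
  n <- 5
  # frames linear in gate time with slope s
  s <- 3e6
  fr <- array(NA_real_, c(n, n, length(gates)))
  for (k in seq_along(gates)) fr[, , k] <- 1 + s * gates[k]
  st <- hyper_stack(fr, gates, 200e-9)
  expect_equal(max(abs(temporal_derivative(st, 1e-6) - s)), 0, tolerance = 1e-6)
  # constant stack -> zero derivative
  st0 <- hyper_stack(array(2, c(n, n, 4)), gates[1:4], 200e-9)
  expect_equal(max(abs(temporal_derivative(st0, 1e-6))), 0)
  expect_error(temporal_derivative(hyper_stack(array(1, c(n, n, 1)), 1e-6, 200e-9),
                                   1e-6), "2 frames")
  # exponential: central difference error within the Taylor remainder bound
  tau <- 1.5e-6
  ste <- exponential_stack(matrix(tau, n, n), gate_times = gates)
  h <- 250e-9
  for (g in gates[2:(length(gates) - 1)]) {
    num <- temporal_derivative(ste, g)[3, 3]
    exact <- -exp(-g / tau) / tau
    bound <- h^2 / 6 * exp(-(g - h) / tau) / tau^3
    expect_lt(abs(num - exact), bound * (1 + 1e-9))
  }
})

test_that("RT recovers the generator diffusivity on exact heat-kernel stacks", {
  alpha <- 1.4e-7
  hk <- heat_kernel_stack(alpha, sigma0 = 1.5e-6, grid_size = 121,
                          pixel_size = 100e-9)
  ctr <- data.frame(x_px = 61, y_px = 61)
  for (g in c(1e-6, 1.25e-6, 1.5e-6)) {
    est <- compute_rt(hk, g, locations = ctr)
    expect_true(est$valid)
    expect_equal(est$rt, alpha, tolerance = 0.02)
  }
  # ratio invariance under positive rescaling (gain/unit changes)
  hk2 <- hk; hk2$frames <- hk2$frames * 1234
  expect_equal(compute_rt(hk2, 1.25e-6, locations = ctr)$rt,
               compute_rt(hk, 1.25e-6, locations = ctr)$rt, tolerance = 1e-12)
  # graceful degradation with coarser pixels: still near alpha
  hkc <- heat_kernel_stack(alpha, sigma0 = 1.5e-6, grid_size = 31,
                           pixel_size = 400e-9)
  est_c <- compute_rt(hkc, 1.25e-6, locations = data.frame(x_px = 16, y_px = 16))
  expect_equal(est_c$rt, alpha, tolerance = 0.1)
})

test_that("low-|Laplacian| estimates are flagged invalid, not divided", {
  hk <- heat_kernel_stack(1.4e-7, sigma0 = 1.5e-6, grid_size = 61,
                          pixel_size = 200e-9)
  # inflection ring: Laplacian changes sign near r = sqrt(2) sigma
  est <- compute_rt(hk, 1.25e-6, lap_floor_quantile = 0.8)
  expect_true(any(!est$valid))
  expect_true(all(is.na(est$rt[!est$valid])))
  flat <- hyper_stack(array(1, c(8, 8, 3)), c(1, 2, 3) * 1e-6, 200e-9)
  expect_warning(compute_rt(flat, 2e-6), "no valid")
})

test_that("the cold water side has a higher RT than absorber hotspots", {
  st <- interface_stack()
  # hotspot 1 um inside the bundle; water point ~1 um beyond the interface
  locs <- data.frame(x_px = c(33, 43), y_px = c(38, 38))
  for (g in c(0.75e-6, 1.25e-6, 1.75e-6)) {
    est <- compute_rt(st, g, locations = locs, lap_floor_quantile = 0)
    expect_true(all(est$valid))
    expect_gt(est$rt[2], est$rt[1])
  }
})

test_that("Laplacian peak finding is deterministic with separation pruning", {
  xy <- seq(-10, 10)
  bump <- function(x0, y0, a, s = 2) a * exp(-(outer((xy - y0)^2, (xy - x0)^2, `+`)) / (2 * s^2))
  one <- laplacian2d(bump(0, 0, 10), 1)
  pk <- find_laplacian_peaks(one, min_separation = 3)
  expect_equal(pk[1, c("x_px", "y_px")], data.frame(x_px = 11, y_px = 11))
  # two bumps beyond the separation: both retained
  two <- laplacian2d(bump(-5, 0, 10) + bump(5, 0, 8), 1)
  pk2 <- find_laplacian_peaks(two, min_separation = 4)
  expect_gte(nrow(pk2), 2)
  expect_setequal(pk2$x_px[1:2], c(6, 16))
  # closer than the separation: the strongest survives and no kept pair
  # is within the exclusion radius
  close2 <- laplacian2d(bump(-1, 0, 10) + bump(2, 0, 8), 1)
  pk3 <- find_laplacian_peaks(close2, min_separation = 8)
  expect_gte(nrow(pk3), 1)
  expect_equal(pk3$value[1], max(abs(close2), na.rm = TRUE))
  if (nrow(pk3) > 1) {
    d <- as.matrix(dist(pk3[, c("x_px", "y_px")]))
    expect_true(all(d[upper.tri(d)] >= 8))
  }
  # flat frame: no peaks
  expect_equal(nrow(find_laplacian_peaks(matrix(1, 9, 9), 3)), 0L)
})

test_that("regional box statistics follow the documented percentile rule", {
  est <- data.frame(region = "water", gate_time_s = 1e-6,
                    x_px = 1:4, y_px = 1, dBC_dt = 0, laplacian = 1,
                    rt = c(1, 2, 3, 4) * 1e-7, valid = TRUE)
  box <- aggregate_rt(est)
  expect_equal(box$mean, 2.5e-7)
  # type-7 linear interpolation between order statistics
  expect_equal(box$q25, unname(quantile(c(1, 2, 3, 4) * 1e-7, 0.25, type = 7)))
  expect_equal(box$q75, unname(quantile(c(1, 2, 3, 4) * 1e-7, 0.75, type = 7)))
  # identical estimates collapse the box
  est2 <- est; est2$rt <- 5e-7
  box2 <- aggregate_rt(est2)
  expect_equal(c(box2$mean, box2$q25, box2$q75), rep(5e-7, 3))
  expect_warning(aggregate_rt(rbind(est, data.frame(region = "empty", gate_time_s = 1e-6,
                                                    x_px = 9, y_px = 9, dBC_dt = 0,
                                                    laplacian = 0, rt = NA, valid = FALSE))),
                 "omitted")
})

test_that("two-region stacks preserve the generator diffusivity ordering", {
  # two independent heat kernels with alpha1 < alpha2, evaluated regionally
  a1 <- 1.0e-7; a2 <- 1.6e-7
  hk1 <- heat_kernel_stack(a1, sigma0 = 1.5e-6, grid_size = 61, pixel_size = 150e-9)
  hk2 <- heat_kernel_stack(a2, sigma0 = 1.5e-6, grid_size = 61, pixel_size = 150e-9)
  frames <- array(NA_real_, c(61, 122, length(hk1$gate_times)))
  frames[, 1:61, ] <- hk1$frames
  frames[, 62:122, ] <- hk2$frames
  st <- hyper_stack(frames, hk1$gate_times, 150e-9)
  labels <- matrix(rep(c("slow", "fast"), each = 61 * 61), 61, 122)
  box <- suppressWarnings(rt_region_stats(st, labels, lap_floor_quantile = 0.9))
  expect_equal(box$mean[box$region == "slow"], a1, tolerance = 0.1)
  expect_equal(box$mean[box$region == "fast"], a2, tolerance = 0.1)
  expect_gt(box$mean[box$region == "fast"], box$mean[box$region == "slow"])
})

test_that("interface disc features reduce the cold-side RT and create double-exponential decays", {
  m <- mats0()
  feats <- lapply(c(3e-6, 5.5e-6, 8e-6, 10.5e-6, 13e-6), function(y)
    list(center = c(8.2e-6, y), radius = 0.5e-6,
         props = material_props("feature", 2.6e5, 1.0e-7, 3.4e6)))
  st_mat <- material_props("surrounding_tissue", 0.9e5, 1.1e-7, 3.6e6)
  sc <- sim_config(total_time = 2.5e-6)
  pr <- probe_model()
  stk <- function(ph) build_stack(simulate_temperature_field(ph, pump_pulse(), sc),
                                  pr, gate_times = seq(0, 2e-6, by = 250e-9))
  sf <- stk(build_interface_phantom(side_a_props = m$axon_bundle,
                                    side_b_props = st_mat, features = feats))
  sp <- stk(build_interface_phantom(side_a_props = m$axon_bundle,
                                    side_b_props = st_mat))
  locs <- data.frame(x_px = 48, y_px = 28)   # cold side, ~1 um beyond the discs
  g5 <- seq(0.75e-6, 1.75e-6, by = 250e-9)
  rt_f <- vapply(g5, function(g)
    compute_rt(sf, g, locations = locs, lap_floor_quantile = 0)$rt, numeric(1))
  rt_p <- vapply(g5, function(g)
    compute_rt(sp, g, locations = locs, lap_floor_quantile = 0)$rt, numeric(1))
  expect_lt(mean(rt_f), mean(rt_p))

  # with per-region out-of-plane loss the trace at a feature shows a
  # separated fast + slow decay, preferred over a single exponential
  mv <- st_feature_movies()$feat
  tr <- movie_to_trace(mv, pr, c(41, 28))
  fit <- fit_double_exponential(tr, window = c(0.5e-6, 2.5e-6))
  expect_identical(fit$preferred, "double")
  expect_lt(fit$tau_fast / fit$tau_slow, 0.5)
})
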