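# Shared fixtures, built in code. Simulations are cached per test run so
# several test files can reuse the same phantom stack without re-solving.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# materials without out-of-plane loss: clean in-plane diffusion physics
mats0 <- function() phantom_materials()

# materials with per-region out-of-plane loss calibrated to the bulk decay
# scales (water 1.5 us, bundle/tissue 1.9 us)
mats_loss <- function() {
  list(
    water = material_props("water", 1.0e5, 1.4e-7, 4.18e6, loss = 1 / 1.5e-6),
    axon_bundle = material_props("axon_bundle", 2.2e5, 1.1e-7, 3.6e6, loss = 1 / 1.9e-6),
    surrounding_tissue = material_props("surrounding_tissue", 0.9e5, 1.1e-7, 3.6e6,
                                        loss = 1 / 1.9e-6),
    feature = material_props("feature", 2.6e5, 1.0e-7, 3.4e6, loss = 1 / 1.9e-6)
  )
}

# canonical bundle/water interface phantom (15 x 15 um, 200 nm px)
interface_phantom <- function() {
  m <- mats0()
  build_interface_phantom(side_a_props = m$axon_bundle, side_b_props = m$water)
}

interface_stack <- function() cached("interface_stack", {
  mv <- simulate_temperature_field(interface_phantom(), pump_pulse(),
                                   sim_config(total_time = 2.5e-6))
  build_stack(mv, probe_model(), gate_times = seq(0, 2e-6, by = 250e-9))
})

# surrounding-tissue interface with ~1 um absorbing disc features on the
# cold side, plus the matching plain interface; with per-region loss
st_feature_movies <- function() cached("st_feature_movies", {
  m <- mats_loss()
  feats <- lapply(c(3e-6, 5.5e-6, 8e-6, 10.5e-6, 13e-6), function(y)
    list(center = c(8.2e-6, y), radius = 0.5e-6, props = m$feature))
  sc <- sim_config(total_time = 2.5e-6)
  ftimes <- seq(0, 2.5e-6, by = 25e-9)
  list(
    feat = simulate_temperature_field(
      build_interface_phantom(side_a_props = m$axon_bundle,
                              side_b_props = m$surrounding_tissue,
                              features = feats),
      pump_pulse(), sc, frame_times = ftimes),
    plain = simulate_temperature_field(
      build_interface_phantom(side_a_props = m$axon_bundle,
                              side_b_props = m$surrounding_tissue),
      pump_pulse(), sc, frame_times = ftimes))
})

demo_config_path <- function() {
  system.file("extdata", "demo_interface.yaml", package = "boxtherm")
}
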