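# Demo: axon-bundle / saline interface with small absorbing inclusions
# near the boundary. 15 x 15 um field at 200 nm pixels, one 500 ns pump
# pulse, boxcar gates 0-2 us in 250 ns steps. Per-region out-of-plane loss
# rates encode the finite water-layer thickness and set the bulk decay
# scales (water 1.5 us, bundle 1.9 us).
seed: 1
output_dir: demo_out
phantom:
  field_um: [15, 15]
  pixel_size_nm: 200
  interface_um: 7.5
  side_a:
    material: axon_bundle
    loss_per_s: 5.2632e+5       # 1 / 1.9 us
  side_b:
    material: water
    loss_per_s: 6.6667e+5       # 1 / 1.5 us
  features:                    # lipid-rich ~1 um inclusions near the boundary
    - {center_um: [6.8, 3.0], radius_um: 0.5, material: feature,
       absorption: 4.4e+5, diffusivity: 0.9e-7, heat_capacity: 3.4e+6,
       loss_per_s: 5.2632e+5}
    - {center_um: [6.8, 6.0], radius_um: 0.5, material: feature,
       absorption: 4.4e+5, diffusivity: 0.9e-7, heat_capacity: 3.4e+6,
       loss_per_s: 5.2632e+5}
    - {center_um: [6.8, 9.0], radius_um: 0.5, material: feature,
       absorption: 4.4e+5, diffusivity: 0.9e-7, heat_capacity: 3.4e+6,
       loss_per_s: 5.2632e+5}
    - {center_um: [6.8, 12.0], radius_um: 0.5, material: feature,
       absorption: 4.4e+5, diffusivity: 0.9e-7, heat_capacity: 3.4e+6,
       loss_per_s: 5.2632e+5}
pulse:
  duration_ns: 500
  period_us: 10
  spot_fwhm_um: 6
  peak_heating_rate: 1.0e+8
sim:
  total_time_us: 2.5
  boundary: fixed_ambient
  pump_mode: uniform
  pad_um: 5
detection:
  probe_fwhm_um: 1
  gain_mv_per_k: 1
  noise_std_single_mv: 0
  n_periods: 2040
  gate_width_ns: 250
  gate_start_us: 0
  gate_stop_us: 2
analysis:
  cv_window_us: [0.75, 2]
  tau_window_us: [0.5, 2]
  rt_gate_times_us: [0.75, 1.0, 1.25, 1.5, 1.75]
  laplacian_floor_quantile: 0.8
  mean_floor_frac: 0.01
trace_points:
  - {x_px: 33, y_px: 38, name: A1}
  - {x_px: 15, y_px: 38, name: A2}
  - {x_px: 44, y_px: 38, name: Water}
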