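# boxtherm

Time-resolved mid-infrared photothermal microscopy resolves *thermal
transients*: a pulsed mid-IR pump heats whatever absorbs, a focused probe
reads the resulting signal, and a high-speed boxcar (gated integrator)
samples the heating-and-cooling curve at nanosecond gate delays. Sweeping
the gate start time `t_g` while raster scanning produces a
**hyper-temporal image stack** — one image per time point of the thermal
decay. In water-rich biological samples (axon bundles in saline, tissue),
where water absorbs as strongly as the specimen, it is the *decay
dynamics*, not the amplitude, that separate sample from bath.

`boxtherm` is an R package for analysing such stacks, for researchers in
photothermal/phototransient imaging who need reproducible, tested
implementations of the field's transient statistics:

* **CV mapping** — per pixel, `CV = sigma/|m|` across the stack's frames
  (population convention). Fast-decaying regions light up; a water
  background forms a homogeneous band near `CV ~ 0.3` over the diffusion
  window.
* **Decay times** — the 1/e peak-to-minimum rule
  `tau_d`: the time for the post-peak signal to fall by a 1/e margin of the
  peak-to-minimum span (`extract_tau()`, `map_tau()`), and least-squares
  double-exponential fits `a e^{-t/tau_fast} + b e^{-t/tau_slow} + c` for
  interfaces with thermal-resistance delays (`fit_double_exponential()`).
* **Rate of transfer** — in analogy with the heat equation,
  `RT = (dBC/dt) / (nabla^2 BC)` in m²/s from the stack's temporal
  derivative and 2-D Laplacian (`compute_rt()`), with Laplacian-peak
  location and regional 25–75% box statistics (`aggregate_rt()`). On an
  exact heat-kernel field, RT equals the thermal diffusivity.
* **Supporting operations** — boxcar gating with half-open windows,
  first-harmonic lock-in demodulation, linescan SNR and FWHM, median
  background subtraction, shortest-interval dispersion summaries.
* **A synthetic microscope** — material phantoms with a straight
  absorber/water interface and disc features, an explicit
  flux-conservative 2-D heat solver (500 ns pulses, 100 kHz), Gaussian
  probe sampling, gating, and period-averaged noise — so every statistic
  is validated against known ground truth.

## Worked example

```r
library(boxtherm)

# a noiseless water-like transient: BC(t) = exp(-t / 1.5 us)
tr <- exp_decay_trace(1.5e-6, times = seq(0, 10e-6, by = 1e-8))
extract_tau(tr)
#> decay_fit (1/e peak-to-minimum): tau_d = 1.497 us
#> peak 1 mV at 0 us; floor 0.001273 mV

# a tissue-side transient behind small features: 200 ns then 1.2 us
fit_double_exponential(double_exp_trace(200e-9, 1.2e-6))
#> decay_fit (double exponential): tau_fast = 200 ns, tau_slow = 1.2 us
#> amplitudes 1 / 1 mV, offset -1.39e-09 mV; preferred model: double

# CV of that water transient over the six diffusion-window gates
st <- exponential_stack(matrix(1.5e-6, 3, 3),
                        gate_times = seq(0.75e-6, 2e-6, by = 250e-9))
compute_cv_image(st, c(0.75e-6, 2e-6))
#> cv_image: 3 x 3 px over t_g = 7.5e-07 - 2e-06 s (6 frames, population sd)
#> valid pixels: 9/9; CV range 0.282 - 0.282
```

The extracted constant (1.497 us) reproduces the generator's 1.5 us to
within one 10 ns sample; the double fit recovers both constants exactly on
noiseless data; and a pure 1.5 us exponential yields `CV = 0.282` over the
0.75–2 us window — the ~0.3 water signature.

End-to-end, the packaged demo simulates a 15 × 15 um bundle/saline
interface with ~1 um inclusions and summarises each region:

```r
demo <- system.file("extdata", "demo_interface.yaml", package = "boxtherm")
run_cli(c("report", "--config", demo))
#> region summary (median CV, median tau, mean RT):
#>       region cv_median tau_median_us rt_mean_m2_s n_px
#>  axon_bundle    0.2248        0.8060    9.117e-07 2711
#>      feature    0.2870        0.7291    6.378e-07   64
#>        water    0.2843        0.7647   -9.704e-07 2850
```

Small inclusions decay fastest, water next, the bundle interior slowest —
the volume-to-surface scaling `tau ~ C_V V / (h A)` made spatial
(`predict_feature_tau()`), with CV mirroring the decay times.

A command-line wrapper is installed as `boxtherm`
(subcommands `simulate`, `trace`, `cv`, `tau`, `rt`, `snr`, `report`); all
runs are seeded and log a config hash. Stacks travel as multi-page 32-bit
float TIFF plus a JSON sidecar (`write_stack()` / `read_stack()`), traces
and maps as CSV.

See the methods vignette
(`vignettes/boxcar-photothermal-methods.Rmd`) for the model, the numerical
choices, and known limitations.

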