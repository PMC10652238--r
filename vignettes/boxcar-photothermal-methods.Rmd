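---
title: "Methods: time-resolved photothermal stack analysis with boxcar gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved photothermal stack analysis with boxcar gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxtherm)
```

## The measurement this package models

In mid-infrared photothermal microscopy a pulsed infrared pump beam heats
the sample wherever it absorbs; a co-focused visible/near-infrared probe
senses the resulting refractive-index change as a modulation of its
backscatter. A high-speed boxcar (gated integrator) averages the probe
signal over a short gate window delayed by `t_g` relative to the pump
pulse, minus a baseline window placed where no signal is present. Sweeping
`t_g` yields a trace of the heating-and-diffusion transient at one
location; raster-scanning the sample at a sequence of gate delays yields a
*hyper-temporal stack* — one image per time point of the thermal transient.
Water-rich biological samples absorb strongly in the mid-IR, so amplitude
contrast alone often cannot separate a specimen from its bath; the
*transient dynamics* (how fast each pixel's signal decays) can.

`boxtherm` implements the analysis of such stacks — per-pixel
coefficient-of-variance (CV) maps, 1/e and double-exponential decay times,
linescan widths, and a Laplacian-based rate-of-transfer estimator —
together with a physics-based synthetic generator that stands in for the
microscope, so every statistic can be validated against known ground
truth.

## The forward model

### Sample phantoms

A `thermal_phantom` is a set of aligned per-pixel maps: absorption
coefficient (1/m), thermal diffusivity `alpha` (m^2/s), volumetric heat
capacity `C_V` (J m^-3 K^-1), and a region label. The packaged defaults
(`phantom_materials()`) use textbook water constants (`alpha = 1.4e-7`,
`C_V = 4.18e6`, absorption 1e5 1/m, i.e. 1000 1/cm at a protein band) and
protein-rich soft-tissue values for the absorber (`alpha = 1.1e-7`,
`C_V = 3.6e6`, absorption 2.2x water, matching the observed amplitude
ratio between bundle and bath). `build_interface_phantom()` places a
straight vertical interface with optional disc features — the canonical
field is 15 x 15 um at 200 nm pixels (75 x 75).

### Heating and diffusion

`simulate_temperature_field()` integrates the in-plane heat equation

    d(DT)/dt = (1/C_V) div(k grad DT) + S/C_V - loss * DT,   k = alpha * C_V

with a source `S = peak_heating_rate * absorption * profile` active for
the pulse duration (default 500 ns at a 100 kHz repetition rate) and zero
afterwards. Three numerical choices matter:

* **Flux-conservative form.** The divergence form with harmonic-mean face
  conductivities is used rather than `alpha * laplacian(DT)`. The two
  coincide for homogeneous media, but only the flux form conserves
  `sum(C_V * DT) * dx^2` exactly across material interfaces — the
  conservation test demands drift below 1e-6 per step (measured: round-off,
  ~1e-16).
* **Explicit stepping.** Forward-time centred-space with the stability
  bound `dt <= dx^2 / (4 max alpha)`; the default step is half the bound,
  capped at 25 ns so the pump pulse is resolved. Explicit stepping keeps
  the scheme transparent and makes conservation trivially checkable;
  the grids involved (~100 x 100, a few hundred steps) make implicit
  solvers unnecessary.
* **Boundaries.** `fixed_ambient` pads the phantom by 5 um of replicated
  edge material and clamps the outer ring to ambient; within the 2.5 us
  simulated span the thermal diffusion length (~0.8 um) keeps this ring
  invisible to the analysed field. `insulated` (mirror cells) exists for
  conservation tests.

One pulse is simulated per run: with decay constants at or below ~2 us the
sample relaxes fully within the 10 us repetition period, so steady-state
accumulation is negligible by construction.

### The out-of-plane loss term

A strictly 2-D simulation cannot decay a spatially uniform heated region at
all — in the instrument, uniform regions cool by conduction *normal to the
imaging plane* into the bath and windows, at a rate set by the local column
(water-layer thickness, sample geometry) that no in-plane map can supply.
The first-order loss term stands in for that channel. It defaults to 0
(clean in-plane physics, used by all oracle tests) and may be a scalar or a
per-region value via `material_props(..., loss = )`: the demo
configuration assigns `1/1.5 us` to water and `1/1.9 us` to the bundle,
reproducing the observed bulk decay scales of the two environments. This
calibration is a generator design choice, made once; the analysis code
never sees it.

### Detection

The probe samples the temperature field through a 2-D Gaussian kernel of
the probe-spot FWHM (default 1 um; the 6 um pump is treated as flat across
the field — `co_scanned` mode re-centres the pump per pixel for small
phantoms when the scanning geometry itself is under study). The signal is
`gain` mV per kelvin of probe-weighted temperature rise; there is no depth
sectioning. Boxcar semantics are bit-reproducible: windows are half-open
`[start, start + width)` on sample timestamps (10 ns grid), the default
gate width is 250 ns (half the pump pulse), and

    BC = | mean(gate window) - mean(baseline window) |

with the absolute value applied after baseline subtraction, as in the
imaging convention. Simulated traces have an exactly zero pre-pulse
baseline, so the baseline window defaults to "none" (zero reference); on
full-period instrument-style traces the last 1 us of the 10 us period is
the natural choice. Detection noise is injected *after* averaging, as
zero-mean Gaussian noise of standard deviation `noise_std_single /
sqrt(n_periods)` (default 2040 periods): statistically identical to
simulating every period, three orders of magnitude cheaper. Lock-in
demodulation uses the peak (not RMS) amplitude convention — a pure
`A sin(2 pi f t)` returns `A` — because reported mV levels depend on this
otherwise-arbitrary calibration.

For signal-to-noise comparisons between gating strategies the package
adopts a readout-noise model: each per-pixel estimate (peak-gated boxcar,
whole-trace mean) carries the same noise floor, so SNR ordering reduces to
signal ordering, where the peak-gated mean always dominates for a pulsed
decaying waveform. The `sqrt(N)` period-averaging law is checked by direct
Monte-Carlo.

## The analysis statistics

### Coefficient of variance

Per pixel, `CV = sigma / |m|` over the frames of a chosen gate-time
window, with the *population* standard deviation (divide by n). The sample
convention would move a water-like value from ~0.28 to ~0.31 — both round
to the ~0.3 headline — so the convention is recorded in the object. The
window is deliberately a required argument: including heating-phase frames
(before `t_g ~ 0.5-0.75 us`) changes CV levels, and the diffusion-window
convention is the documented recommendation. Pixels whose |mean| falls
below 1% of the windowed global maximum are masked rather than divided —
CV is meaningless where there is no signal.

### 1/e decay time

`tau_d` is the time after the peak at which the signal first falls to
`min + (peak - min)/e`, with the crossing linearly interpolated. The one
subtle choice is the reference minimum. For a trace that decays out inside
the analysed window (any full-period trace), the window minimum *is* the
floor and the estimator recovers a pure exponential's constant to within a
sample. For short windows the window minimum overestimates the floor and
biases `tau_d` low — a 1.5 us constant read from a 0-2 us window would be
compressed by tens of percent. `floor` is therefore an explicit argument:
`"window"` by default, or a number when the floor is known (0 for
synthetic traces generated with a zero baseline, as in the acceptance
recomputations). Signals that never reach the 1/e level are flagged
invalid, never extrapolated. `map_tau()` applies the extractor per pixel
and records the same-window CV so the CV-tau anticorrelation — high CV
marking fast decays and vice versa — can be computed directly; on
noiseless monotone-decay phantoms the Spearman correlation is exactly -1.

### Double-exponential fits

`fit_double_exponential()` fits `a exp(-t/tau_fast) + b exp(-t/tau_slow) +
c` to the post-peak samples by variable projection (for fixed constants
the amplitudes are linear) over a log-spaced grid of constant pairs,
refines the best starts with Nelder-Mead on the projected objective, and
polishes with Levenberg-Marquardt. Constants are ordered after the fit.
Identifiability: fits with `tau_fast / tau_slow > 0.5`, or with a
negligible component amplitude, or that do not beat the single-exponential
projection, are reported with `preferred = "single"` — two constants
closer than a factor of two are not meaningfully resolved by these data.
Noiseless recovery of (200 ns, 1.2 us) is exact to ~1e-6; with 1% noise
the median recovery over 50 seeds stays within 10%.

### Linescan widths

`fwhm_linescan()` references the half level to the local baseline (mean of
the two flanking minima), interpolates crossings linearly, and resolves
exact-tie plateaus toward the wider width. On simulated diffusion the
measured widths track the closed form `FWHM^2(t) = FWHM^2(0) + 16 ln2
alpha t` to better than 1% on a 100 nm grid.

### Dispersion intervals

Statements like "75% of the water CV values fall between a and b" do not
pin down an interval convention, so `dispersion_summary()` reports the
*shortest* interval containing the requested mass (default) alongside the
central symmetric-percentile interval, labelled, with type-7 quantiles
throughout.

### Rate of transfer

By analogy with the heat equation, the rate of transfer is

    RT = (dBC/dt) / laplacian(BC)      [m^2/s]

with the temporal derivative a central difference across adjacent frames
(250 ns spacing, no smoothing by default) and the Laplacian the 5-point
stencil (9-point available), border masked. At a decaying local maximum
both numerator and denominator are negative, so RT is positive with no
extra sign convention. On an exact heat-kernel stack the identity
`dT/dt = alpha laplacian(T)` makes RT equal the generator diffusivity —
the module's central correctness oracle, satisfied within 0.2% on a 100 nm
grid (2% asserted) and degrading gracefully with pixel size. Estimates
where `|laplacian|` falls below an adaptive floor (default: the 80th
percentile of the frame's `|laplacian|`) are flagged invalid rather than
divided — the ratio blows up on inflection lines, which is why point
estimates are taken at Laplacian *peaks* (`find_laplacian_peaks()`: local
maxima of `|laplacian|` above a quantile threshold, greedily thinned by a
minimum separation, strongest first, deterministic order).
`aggregate_rt()` pools valid estimates per region across the
diffusion-window gate times (default five points over 0.75-2 us) and
reports mean and 25-75% margins with type-7 quantiles.

Note that where the out-of-plane loss term is active, `RT` at points of
*positive* Laplacian (the cold side of a strong interface) can turn
negative — the loss channel removes heat faster than in-plane curvature
supplies it. The ordering properties asserted by the test-suite
(cold-side RT above hotspot RT; feature-backed interfaces below plain
ones) are therefore evaluated on loss-free phantoms, where RT cleanly
estimates the local diffusivity.

## What the generator does and does not emulate

The synthetic module reproduces: the 15 x 15 um field at 200 nm pixels,
500 ns pulses at 100 kHz, 250 ns boxcar gates over 0-2 us (9 frames),
single-exponential decays spanning 0.9-1.9 us across regions,
double-exponential cold-side transients behind ~1 um disc features, and
period-averaged Gaussian noise. It does not emulate: 3-D optics or probe
propagation, depth sectioning, window/sample thermal coupling, multi-pulse
steady-state accumulation, electronic transfer functions, phase noise, or
detector nonlinearity. Passing tests therefore validate the *analysis
chain* against controlled thermal physics; they do not certify performance
on instrument data with, e.g., correlated noise or defocus.

## Problem sizes and determinism

The test-suite simulations use 75 x 75 to 151 x 151 grids with a few
hundred explicit steps each (seconds per run); Monte-Carlo checks use 50
seeds for double-exponential recovery and 1e5 draws for the noise law. All
stochastic draws flow from a single integer seed; identical configuration
plus seed yields byte-identical CSV and TIFF outputs (`run_cli()` logs a
config hash and seed with every run). Stacks are stored as multi-page
32-bit IEEE-float TIFF (written by a minimal built-in baseline-TIFF
writer, since the available TIFF writer stores integer samples only) with
a JSON sidecar carrying gate times, gate width, pixel size and seed;
round-trips are bit-exact at float32 precision.

## Known limitations

* The 2-D solver plus scalar/region loss is a surrogate for 3-D heat
  escape; absolute decay constants from the simulator are calibrated, not
  predicted.
* `extract_tau` with the default window floor is biased low when the
  analysed window does not contain most of the decay; supply the floor or
  lengthen the window when absolute constants matter.
* Double-exponential constants closer than a factor of two are reported
  as effectively single-exponential by design.
* RT sign and normalisation follow the diffusion-equation analogy above;
  where loss dominates in-plane curvature the pointwise estimate is not a
  diffusivity.
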