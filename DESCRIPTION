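Package: boxtherm
Title: Time-Resolved Photothermal Image Stack Analysis with Boxcar Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of time-resolved mid-infrared photothermal microscopy
    data acquired with high-speed boxcar (gated-integrator) detection.
    Provides a physics-based synthetic-data generator (pulsed heating and
    two-dimensional heat diffusion over material phantoms) with a detection
    model (Gaussian probe sampling, boxcar gating, lock-in demodulation,
    period-averaged noise), assembly of hyper-temporal image stacks, per-pixel
    coefficient-of-variance mapping, 1/e and double-exponential decay-time
    extraction and mapping, full-width-at-half-maximum linescan analysis,
    median background subtraction, and a Laplacian-based rate-of-transfer
    estimator with regional box statistics. Stacks are exchanged as multi-page
    32-bit float TIFF files with JSON sidecar metadata; traces and tables as
    CSV. A command-line entry point ties simulation and analysis into
    reproducible, seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
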