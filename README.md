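# opmcal

Characterization and calibration computations for an oblique plane
microscope (OPM) built around a remote-focusing train — the kind of
single-objective light-sheet system where a tilted light sheet is launched
and collected through one high-NA primary objective, relayed into a matched
remote objective, and imaged by a tilted tertiary objective.

The package is aimed at instrument builders who need to answer, with
numbers, the questions that decide whether such a microscope is usable:

* **Design arithmetic.** Remote focusing is aberration-free only when the
  relay magnification equals the immersion-index ratio,
  `M1 (f_design/M2) / f_TL2 = n1/n2`. For a 100X silicone-oil primary
  (n = 1.406) and a 40X air remote objective on the 180 mm tube-lens
  standard this solves to a 320.06 mm remote tube lens. Lateral extents
  demagnify by `1/M`, axial ones by `1/M²`, and the tube-lens pair
  (180/321 mm) makes a ±1 mm focusing excursion of the primary objective
  equivalent to ±3.18 mm of remote-objective displacement.
* **Bead PSF measurement.** Variance-of-Laplacian focus selection, à-trous
  B3-spline wavelet spot detection, and a 2D/1D Gaussian fit cascade
  produce per-bead lateral/axial FWHMs with polar coordinates, summarized
  by radial distance and depth.
* **Remote-volume distortion.** Axial misconjugation of the two objectives
  makes magnification depth-dependent: beads displace radially in
  proportion to their radius. Polar bead matching and origin-constrained
  linear fits yield the percent magnification error per depth, its rate
  (%/µm), and the zero-distortion remote-objective position `D0`.
* **Two-galvo scan calibration.** A mirror voltage-ratio mismatch tilts the
  summed frame intensity linearly across a scan; the zero-slope ratio per
  objective position, fitted over positions, gives the calibration line
  `ratio_opt(z) = a + b·z` that the acquisition software evaluates on the
  fly.
* **Deskew.** The shear map from (scan step, camera Y, oblique axis) to
  cartesian (x, y, z), with a resampler whose output grid needs
  interpolation only along the scan axis (Catmull-Rom by default).

A synthetic bead-scene simulator with injected ground truth (spatially
varying Gaussian PSF field, radial depth-proportional distortion,
scan-linear illumination gradient, Poisson + read noise) stands in for the
instrument, so every estimator is validated by parameter recovery. See
`vignettes/opm-calibration-methods.Rmd` for the model and all numerical
choices.

## Worked example

```r
library(opmcal)

# Design report for the default train
design_report()$f_tl2_ideal_mm   # 320.0569

# Simulate a coverslip bead field and measure its PSFs
truth <- generate_bead_field(fov = c(70, 70, 0), n_beads = 500,
                             min_separation = 2, seed = 11)
stack <- render_stack(truth, stack_geometry(739, 739, 54),
                      noise_model(TRUE, 1.6), seed = 12)
rec <- measure_psfs(stack)
ok  <- rec[rec$fit_ok, ]
mean(ok$fwhm_lat); mean(ok$fwhm_z)
```

Running the numbered drivers under `analysis/` reproduces the full
characterization; their printed findings (one core, a few minutes each):

```
$ Rscript analysis/02_psf_characterization.R
  500 detections, 500 usable fits
  lateral FWHM 258 +/- 5 nm, axial 699 +/- 14 nm (n = 500)

$ Rscript analysis/03_volume_distortion.R
Optimal remote-objective position D0 = 0.399 +/- 0.003 mm (truth 0.4 mm)
Worst |magnification error| within +/- 3 mm of D0, +/- 10 um depth: 0.26%

$ Rscript analysis/04_scan_calibration.R
Calibration: ratio_opt(z) = 1.01374 + 0.00283 z  (injected 1.01400 + 0.00280 z)

$ Rscript analysis/05_oblique_deskew.R
Lateral agreement: +0.04%, axial: -0.39%
```

The PSF means sit on the injected field evaluated at the beads' true
radii/depths (recovery within 2% at peak SNR ≈ 20); the distortion sweep
recovers the injected optimum to ~3 µm against a 0.1 mm requirement; the
calibration line matches the injected map within its fitted uncertainty;
and the deskewed oblique pipeline agrees with the straight-path pipeline on
identical ground truth to a fraction of a percent. Each driver writes its
tables under `results/`.

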