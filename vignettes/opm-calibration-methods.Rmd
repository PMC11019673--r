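---
title: "Methods: characterizing and calibrating an oblique plane microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing and calibrating an oblique plane microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmcal)
```

## The instrument problem

An oblique plane microscope (OPM) uses one high-NA primary objective both to
launch a tilted light sheet and to collect fluorescence. Aberration-free
imaging of the out-of-focus parts of the illuminated plane relies on *remote
focusing*: the primary objective's focal volume is relayed into the space of
a matched second objective, where a tilted, glass-tipped tertiary objective
images the oblique plane onto a camera. Two properties of this train have to
be established quantitatively before the microscope can be trusted:

1. **The remote volume must be an undistorted replica of sample space.**
   That requires the relay magnification to equal the ratio of the immersion
   refractive indices, and it degrades when the primary and remote objectives
   fall out of axial conjugation -- as happens every time the user focuses by
   moving the primary objective.
2. **Scanning must translate the light sheet without tilting it.** With a
   two-galvo scanner near the primary image plane, the axial position of the
   scan pivot is set by the ratio of the two mirror drive amplitudes, so the
   correct ratio depends on where the objective currently sits.

This package implements the computations for both characterizations, plus
the synthetic bead scenes that stand in for the instrument, so that every
estimator can be validated by parameter recovery against known ground truth.

## Design arithmetic

`remote_tube_lens_focal()` solves the index-matching condition
$M_1 (f_\mathrm{design}/M_2) / f_\mathrm{TL2} = n_1/n_2$ for
$f_\mathrm{TL2}$. Objective focal lengths are taken as
$f_\mathrm{design}/M$ with $f_\mathrm{design} = 180$ mm (the tube-length
standard both objectives are specified against); for the 100X silicone-oil
primary ($n_1 = 1.406$) and 40X air remote objective this gives 320.06 mm.
The function reports the exact solution -- rounding to a catalogue value is a
presentation concern. Related one-liners cover lateral ($1/M$) and axial
($1/M^2$) demagnification into sample space, the one-dimensional expansion
of a cylindrical telescope, and the longitudinal relay magnification
$(f_\mathrm{TL2}/f_\mathrm{TL1})^2 = (321/180)^2 = 3.18$ that converts
primary-objective focusing excursions into equivalent remote-objective
displacements. Focal lengths stay in mm (the field's unit for lens
arithmetic); everything downstream of the renderers works in micrometres,
with FWHMs reported in nm.

## The synthetic bead scenes

The simulator emulates the two physical samples used throughout: sparse
100 nm beads immobilized on a coverslip (PSF and distortion measurements)
and a dense bead-in-agarose volume (scan calibration). Its injected model is
deliberately the exact statistical structure the estimators assume, so
recovery tests are well-posed:

* **PSF field.** Each bead renders as a separable 3D Gaussian whose FWHMs
  grow linearly with radial distance $r$ from the image centre and with
  $|z|$: `fwhm = fwhm0 * (1 + radial_growth * r + depth_growth * |z|)`. The
  defaults (255/688 nm at centre, `radial_growth = 6.7e-4`/um,
  `depth_growth_lat = 0.009`/um, `depth_growth_ax = 0.027`/um) reproduce the
  magnitudes of the trends a well-aligned remote-focusing path shows: a few
  percent lateral growth over a 100 um radius and roughly 9%/27%
  lateral/axial growth over 10 um of defocus. A Gaussian (rather than
  diffraction) PSF is used because the estimators are Gaussian fits; any
  non-Gaussian structure would be invisible to the pipeline anyway.
* **Distortion.** Apparent lateral positions scale by
  `1 + distortion_rate * z` about the image centre -- a radial, depth-
  proportional magnification error, which is exactly what axial
  misconjugation produces to first order.
* **Illumination gradient.** In an oblique scan at voltage ratio $\rho$ and
  objective position $z$, frame $s$ (0-based, $n$ steps) is scaled by
  $1 + G\,(\rho - \rho_\mathrm{opt}(z))\,(s - (n-1)/2)$ with
  $\rho_\mathrm{opt}(z) = a + b z$. The injected map defaults to
  $a = 1.014$, $b = 0.0028$/mm, which spans ratios 1.014--1.039 over a 9 mm
  travel -- the magnitude a 15-point sweep from 1.013 to 1.041 is designed to
  bracket.
* **Noise.** Poisson shot noise plus Gaussian read noise
  ($\sigma = 1.6$ counts), clamped at zero counts. The default flux of
  13,000 photons/bead puts the peak pixel near 400 counts, i.e. peak SNR
  $\approx 20$.
* **Determinism.** Every stochastic step takes a seed; identical truth +
  seed gives bit-identical stacks.

Voxel values are point samples of the continuous intensity times the voxel
volume. At the default samplings (about one sigma per voxel) the discrete
sum of a bead equals its flux to better than 0.1%; at the much coarser
1.4 um scan step of the calibration scenes the per-frame sampling phase of
each bead becomes a bona fide noise source, which is physical -- a real scan
samples bead content the same way -- and is treated as such below.

What the simulator does **not** emulate: diffraction sidelobes, light-sheet
propagation and shadowing, vectorial/aberrated PSF shapes, fixed-pattern
camera noise, refractive-index mismatch in the sample. Passing recovery
tests therefore demonstrate that the estimators are correct for the model
they assume, not that the model captures every property of real data.

## Bead measurement cascade

`measure_psfs()` follows the classic bead-stack recipe:

1. **Focus selection** -- `best_focus_frame()` maximizes the variance of the
   discrete 4-neighbour Laplacian (the Pech-Pacheco LAPV measure); exact
   ties break toward the stack centre.
2. **Detection** -- `detect_beads()` computes an a-trous (undecimated)
   B3-spline wavelet decomposition and thresholds plane 2 -- the scale that
   responds to diffraction-limited spots -- at $k = 3$ robust sigmas
   (`mad`). Connected components smaller than `min_area = 12` pixels are
   discarded: pure read noise at this threshold produces clusters of at
   most single-digit areas (measured over hundreds of blank frames), while
   a bead at usable SNR occupies 20+ pixels, so 12 separates the two
   populations with margin on both sides. Candidates are intensity-weighted
   component centroids, deduplicated within 4 px (brightest kept). On a
   noise-free sparse image the plane's `mad` can collapse to zero, so the
   threshold is floored at 2% of the plane maximum.
3. **Lateral fit** -- `fit_bead_2d()` fits an axis-aligned elliptical
   Gaussian plus constant background on an 11 x 11 px ROI (half-width 5 px:
   at least 3x the expected sigma while staying clear of neighbours at the
   enforced separation). Unweighted least squares via `nlsLM`; a record is
   usable only if the optimizer converges away from its bounds, $R^2 \ge
   0.8$, and the centre stays inside the ROI. ROIs clipped by the image
   border are flagged, not fitted.
4. **Axial fit** -- `fit_axial_profile()` samples every frame at the fitted
   sub-pixel position (bilinear interpolation) and fits a 1D Gaussian plus
   offset; profiles peaking within 2 frames of the stack boundary are
   flagged. At the standard 54 x 150 nm sampling a 700 nm axial FWHM has
   4-5 points above half maximum.
5. **Refit** -- the lateral fit is repeated at each bead's own best plane,
   and records carry polar coordinates $(r, \theta)$ about the image centre
   (0-based pixel convention, centre at $((n_x-1)/2, (n_y-1)/2)$).

Lateral FWHM is reported per axis and as the x/y mean; summaries use the
mean, the single "XY" number a radial-profile plot needs. FWHM conversion
is the Gaussian $2\sqrt{2\ln 2}\,\sigma$ throughout.

Because the renderer and the fit model agree exactly in the noise-free
limit, the cascade recovers injected FWHMs to machine precision there; the
package's accuracy tests therefore check bias < 0.5% across the 2-8 px FWHM
range and < 2% on mean recovery at SNR 20 with ~500 beads.

## Distortion quantification

For each remote-objective displacement $D$, the coverslip field is measured
at the focal plane ($Z = 0$, the self-reference) and at depths $Z = \pm 5,
\pm 10$ um. `match_beads_polar()` reproduces the polar matching rule: a
probe bead pairs with the reference bead of the same $\theta$ (within a 2
degree tolerance -- the matching is one-to-one, greedily by ascending
$|\Delta r|$). `radial_displacement_rate()` fits $\Delta r$ against $r$
through the origin (a bead at the centre cannot displace radially under a
radial scaling), giving the fractional magnification error at that depth;
`magnification_error_profile()` then fits error-% against $Z$, again through
the origin, giving the error rate in %/um. The sign convention is positive
= apparent magnification increase above the focal plane.
`optimal_remote_position()` fits the rates against $D$ and returns the zero
crossing $D_0$, warning when it extrapolates beyond the sweep.

The emulated sweep injects `distortion_rate = 1e-4 * (D - 0.4)` per um: at
the sweep extremes ($|D - D_0| \approx 5$ mm) the error reaches ~0.5% at 10
um depth, and within routine operation (primary excursions of $\pm 1$ mm
$\approx \pm 3$ mm remote, depths $\le 10$ um) it stays below ~0.3% --
matching the regime the instrument class is reported to occupy. The 0.4 mm
offset emulates a design position estimated from an incomplete optical
model, which the measurement then corrects.

## Scan-ratio calibration

`summed_intensity_series()` sums all pixels per frame (no ROI -- the whole
frame is the signal) and normalizes by the mean over steps;
`slope_for_ratio()` is the OLS slope against 0-based step index, computed
in closed form. `optimal_ratio()` fits slope vs ratio linearly (the
relation is modelled as linear; no higher-order term is offered) and
returns the zero crossing with a delta-method standard error;
`calibration_curve()` fits the per-position optima and exposes
`predict(curve, z)` for on-the-fly use. No dark-level subtraction is done
by default; an optional constant-offset argument exists because a nonzero
offset attenuates normalized slopes (it rescales all slopes of a sweep
equally, so the zero crossing is unaffected).

Two design points deserve note:

* **The same volume is imaged at every ratio of a sweep.** The simulator
  mirrors this (`render_oblique_series()` once per position,
  `apply_scan_illumination()` per ratio). The consequence: the bead-content
  contribution $c$ to the measured slope is common to all ratios, so the
  fitted crossing shifts by exactly $c/G$ -- the experiment's intrinsic
  (and irreducible) per-position error. Averaging over positions, the
  calibration line still recovers the injected $(a, b)$.
* **Conditions sizing.** With 100 steps of 1.4 um, a 32 x 20 um frame at
  0.25 um pixels, bead density 2/um^3 and $G = 0.5$ per (unit ratio x
  step), the predicted standard deviation of $c/G$ is ~2.6e-4 per position,
  giving ~1.6e-4 on the calibration intercept over 10 positions -- the
  a priori variance analysis that sized the default agarose scene. $G$ and
  the density are instrument-specific quantities with no published values;
  they were fixed once from this analysis and from the requirement that a
  mismatched ratio visibly tilts the intensity profile (tens of percent
  across a scan), and are not tuned thereafter.

## Deskew

`oblique_to_cartesian()` is the shear map
$z = x_\mathrm{obl} p_\mathrm{obl} \sin\theta$, $y = y_\mathrm{obl} p_y$,
$x = s\,\Delta x + x_\mathrm{obl} p_\mathrm{obl}\cos\theta$.
`deskew_volume()` inverts it onto a grid chosen so only the scan axis needs
interpolation: the Z voxel is $p_\mathrm{obl}\sin\theta$ (each oblique index
is exactly one Z plane) and the X voxel is the scan step (square XY pixels
when `pixel_y` equals the scan step, the reason for the 117 nm default).
Per Z plane the resampling is a constant-phase fractional shift of the scan
axis.

Interpolation kernels: `nearest`, `linear`, and the default Catmull-Rom
`cubic`. The default matters: at a 117 nm scan step the lateral PSF is
near-Nyquist ($\sigma \approx 1.1$ steps), and a fractional linear
interpolation at phase $\phi$ adds $\phi(1-\phi)\,\Delta x^2$ of variance --
averaged over beads, $\Delta x^2/6$, inflating the fitted X FWHM by ~5-7%.
The Catmull-Rom kernel keeps that broadening well under 1%, preserving the
straight-vs-deskewed FWHM comparison; `nearest` remains available when
strict count preservation is wanted. Interpolated values are clamped at
zero (the cubic kernel's negative lobes can slightly undershoot).

Axis conventions: the scan advances along $+X$; oblique depth increases
toward $+Z$; output metadata records both voxel sizes. A bead's centroid
survives the render-deskew round trip to well under half an output voxel,
and the deskewed cascade agrees with the straight-path cascade on identical
truth to within 3% in FWHM.

## Problem sizes and numerical choices

The shipped tests and analysis scripts use: a 500-bead, 80 x 80 x 8 um
focal-plane scene (739^2 x 54 voxels) for PSF recovery; 120-bead scenes at
501^2 x 24 voxels for each of the 55 stacks of the distortion sweep; 10
agarose volumes of ~90,000 beads (rendered once each) for the calibration
sweep; and a 30-bead oblique scene for the deskew comparison. These sizes
were chosen so each end-to-end analysis completes in a few minutes on one
core while keeping estimator scatter far inside the decision tolerances
(e.g. $D_0$ to ~3 um against a 0.1 mm requirement).

Other numerical details: unweighted least squares everywhere (no weighting
scheme is part of the emulated procedure); `nlsLM` bounds act as quality
gates rather than constraints (a bound-hitting fit is discarded); rejection
sampling for bead separation caps at 200 attempts per bead and reports an
infeasible-density error; all-zero frames in a scan series warn; the
wavelet threshold floor handles the zero-`mad` degenerate case; ties in the
focus metric break toward the stack centre.

## Known limitations

* The Gaussian PSF and linear growth model make the recovery tests
  well-posed but cannot expose estimator biases that only non-Gaussian PSFs
  (aberrations, index mismatch) would produce.
* The distortion model is purely radial; skew or anisotropic magnification
  errors are out of scope, as is any wavefront-level explanation.
* The deskew resamples intensity (interpolation, not flux integration);
  quantitative intensity work across the shear should use `nearest` and
  accept the geometric quantization instead.
* The calibration's per-position error floor is set by bead-content
  statistics ($c/G$); instruments with sparser samples or weaker
  illumination-gradient response (smaller $G$) will see proportionally
  larger scatter in the per-position optima.
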