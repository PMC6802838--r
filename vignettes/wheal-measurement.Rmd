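---
title: "Measuring skin-prick-test wheals from 3D surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring skin-prick-test wheals from 3D surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A skin prick test (SPT) raises small skin swellings — wheals — wherever the
patient reacts to an applied allergen. The clinical readout is each wheal's
longest diameter, with 3 mm or more read as a positive reaction. Wheals are
shallow (0.1–0.5 mm high, 3–12 mm across), fade within the hour, and are
usually measured by eye with a millimetre ruler, which is noisy and poorly
reproducible. Wide-field structured-light scanners can capture the whole
volar forearm as a height map with ~0.01 mm depth accuracy, so the reading
can instead be computed from the 3D topography.

`sptread` implements that computation for regular-grid height maps
(`height_field` objects; mm units, square pixel pitch): it removes the
global arm shape, detects the wheals, fits a parametric surface to each, and
reports the longest diameter. A phantom generator produces synthetic
forearms and the classical validation objects (spherical caps, height
staircases) with exact ground truth, so every stage can be tested
quantitatively without access to patient scans.

## The measurement pipeline

`measure_spt()` chains five stages.

**1. Global surface removal** (`remove_global_surface()`). The height map is
decomposed into a Gaussian–Laplacian pyramid (`n_levels = 7`): Gaussian
levels are successively smoothed and 2x-decimated copies, Laplacian levels
are the details between them, and the top level holds the residual coarse
shape. Collapsing the pyramid with only levels 2–5 retained acts as a
band-pass: the finest levels (sensor noise, pores, follicles) and the
coarsest structure (the arm's cylinder-like global curvature) are zeroed,
leaving the band that carries wheal-scale relief. With the 5-tap binomial
kernels and ~0.2 mm pitch, the kept band spans structure roughly 1–25 mm
across. Keeping all levels reconstructs the input to better than 1e-9 mm
(the pyramid is exact by construction), which the test suite asserts.

**2. Axial background removal.** Band-passing a *curved* surface is not
free: for any smoothing kernel, the detail level of a surface with local
curvature `z''` carries a term proportional to `z'' * (2^l * pitch)^2`, so a
forearm of ~40 mm radius leaves a smooth pedestal of order 1 mm in the kept
band — several times the height of a wheal. Because the forearm is curved
across its axis but nearly straight along it, this pedestal is almost
constant along the arm. The pipeline therefore subtracts, per across-arm
position, the median over the long axis. A wheal occupies a few percent of
the arm's length, so the median is insensitive to it. This step is why a
pure-cylinder phantom comes out flat (RMS below 0.02 mm) even though the
pyramid alone cannot achieve that on curved input.

**3. Wheal detection** (`detect_wheals()`). Candidates are strict 3x3x3
maxima of a stack of scale-normalized Laplacian-of-Gaussian responses,
`-sigma^2 * del^2(G_sigma * S')`, over a geometric ladder of 12 scales with
`sigma` from 1 to 5 mm — via the relation `radius = sigma * sqrt(2)` this
covers diameters of roughly 3–14 mm. Scale normalization makes responses
comparable across scales; for a Gaussian bump of height `h` the centre
response at the matched scale is `h/2` (the closed form
`2 h sigma^2 sigma_b^2 / (sigma^2 + sigma_b^2)^2` is verified to 2% in the
tests), so the default response threshold of 0.03 mm admits bumps upward of
roughly 0.06 mm. Two guards make the detector specific to wheal-like
relief: a Hessian principal-curvature test (ratio bound 10) rejects
ridge-like maxima — residual curvature structure and skin creases are
elongated, wheals are compact — and each response plane has its long-axis
median removed for the same reason as stage 2. Overlapping detections
(circles of radius `sigma * sqrt(2)` overlapping by more than half the
smaller circle) are pruned weakest-first. On 200 synthetic forearms with
4–8 wheals each, detection attains recall at or above 0.95 and precision at
or above 0.9 against ground-truth centres at a 2 mm match radius.

**4. Patch preparation** (`extract_patches()`, `center_patch()`). A square
window of half-width `2 * sigma * sqrt(2)` is cut around each candidate
(clipped windows at the border are flagged, not discarded). Because flat-
topped wheals peak their LoG response near the profile width rather than the
Gaussian relation, the detected scale understates large wheals; once the
bump's extent is measured, the window is re-cut to about 2.6x the shoulder
radius (bounded to 5–14 mm) so the fit sees both the whole bump and clean
background. Within the window, the local skin baseline is removed in two
steps — a plane fitted to the window's outer ring (trimmed of its highest
fifth so a neighbouring bump cannot tilt it), then a quadratic surface
fitted to the non-elevated background cells, since the curvature pedestal is
locally quadratic rather than planar. Elevated cells connected to a
*different* component than the candidate centre (a neighbouring wheal
leaking into the window) are excluded. Finally the points are centred on
the height-weighted centre of mass, and the principal axis of the weighted
second moments provides the initial rotation angle.

**5. Parametric fitting** (`fit_wheal()`). Two surface models are fitted in
a rotated frame (`x' = x cos(theta) - y sin(theta)`,
`y' = x sin(theta) + y cos(theta)`; `theta` is itself a parameter):

* Model 1, an inverted elliptical paraboloid
  `f1 = -(1/c)((x'-x0')^2/wx^2 + (y'-y0')^2/wy^2) + beta`, whose zero-level
  set is an ellipse with semi-axes `a = wx sqrt(beta c)`,
  `b = wy sqrt(beta c)`; the reported diameter is `max(2a, 2b)`. Since the
  paraboloid diverges downward, residuals are evaluated only on cells above
  5% of the patch peak plus a one-pixel annulus — an unweighted full-window
  fit would let the flat background dominate and shrink the ellipse.
* Model 2, a 2D super-Gaussian
  `f2 = gamma exp(-((x'-x0')^2/(2 sx^2))^bx - ((y'-y0')^2/(2 sy^2))^by)`,
  whose exponents flatten the top the way real wheals are flattened; the
  diameter is `max(4 sx, 4 sy)`.

Optimization is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`; centres within the window, widths in [0.25, 15] mm,
flatness exponents in [0.5, 10], `theta` in [-pi/2, pi/2), parameter and
cost tolerances 1e-8, at most 500 iterations, one deterministic restart at
`theta + 45` degrees if the first attempt fails). The axis-swap degeneracy
is resolved by relabelling so the x width is the larger one. A fit that
fails to converge, or lands outside the plausible 1–20 mm diameter range,
falls back to the detection-scale diameter `2 sqrt(2) sigma` and is flagged.

One subtlety: a patch cut from the band-passed surface has lost the finest
pyramid levels, i.e. it is the true relief smoothed by the level-cut kernel
(equivalent Gaussian SD `pyramid_cut_sigma()`, about 0.63 mm at 0.2 mm
pitch for the default kernels). The pipeline therefore convolves the model
with that Gaussian inside the residual, so the recovered parameters describe
the *unsmoothed* wheal. Without this, small wheals read ~0.5 mm too wide.
Standalone `fit_wheal()` calls default to no smoothing, which is the right
setting for surfaces that never passed through the pyramid; on directly
sampled noiseless model surfaces both models then recover their generating
parameters to 0.1%.

The positivity flag (diameter at or above 3 mm, configurable) is a report
column, not a filter: sub-visual wheals that a physician would miss are
still listed.

## What the phantoms emulate — and what they do not

`make_forearm()` renders a cylinder section of radius 40 mm along the
grid's long axis (the default grid is 900 x 320 px at 0.2 mm pitch, i.e.
180 x 64 mm — the grid must stay on the camera-facing flank of the
cylinder), plus super-Gaussian wheals with longest diameters 3–12 mm,
heights 0.1–0.5 mm, mild elongation (aspect 0.6–1), flatness exponents 1–3
and random orientation, placed at least 15 mm apart and 10 mm from the
border; plus band-limited fine texture (SD 0.02 mm at sub-millimetre
scales, standing in for pores and follicles, which the pyramid discards)
and white sensor noise of SD 0.01 mm, the depth accuracy of fringe-
projection scanners of this class. Everything is a pure function of
(configuration, seed).

Because the phantom wheals *are* super-Gaussians, model-2 fitting is a
self-consistency exercise while model-1 fitting is a genuine model-mismatch
test. What the phantoms do not emulate: pseudopod-shaped irregular wheals,
hair, perspective distortion, multi-camera merging seams, or skin that
deforms between poses. Passing phantom tests therefore demonstrates the
numerical machinery, not clinical performance on irregular wheals.

`make_spherical_caps()` and `make_steps()` reproduce the classical
validation objects: sphere sections over base circles of known diameter
(sphere radius from the chord–sagitta relation `R = (r^2 + h^2) / (2h)`)
and staircases of 0.100 mm steps. `measure_cap_diameter()` fits a sphere by
linear least squares to the cells above 10% of the local peak (restricted
to the connected region around the hint so a neighbouring cap cannot
contaminate the fit) and intersects it with the base plane — unbiased under
noise, unlike thresholding the footprint. `measure_step_heights()` averages
each labelled band against the reference band. The cap height (2 mm) and
the measurement procedures are this package's choices; published system
validations state the object diameters and accuracy bounds but not the
extraction procedure.

## Reproducibility and agreement statistics

`coefficient_of_variation()` is `100 * SD / mean` with the unbiased
(n-1) standard deviation. `agreement_stats()` performs a Bland–Altman
analysis with differences taken as `reference - estimated` — chosen so that
a negative mean difference means the automated method reads larger than the
reference — and 95% limits of agreement `mean +/- 1.96 SD`
(`limits_of_agreement()`). `pose_reproducibility()` renders one wheal
constellation under five rigid poses (translations up to ±20 mm along the
arm and ±6 mm across it, in-plane rotations up to ±10 degrees, fresh noise
per pose), re-measures each pose with the full pipeline, matches
measurements back to ground truth, and reports the per-wheal CV across
poses. The across-arm translation budget is smaller than the along-arm one
because the grid must stay on the cylinder flank; the constellation (not
the cylinder axis) is rotated, which keeps the surface single-valued while
still exercising orientation-dependent discretization.

## Numerical choices and degenerate inputs

* Border handling: all convolutions extend the grid gradient-preservingly
  (antisymmetric reflection about the edge sample). Plain symmetric
  reflection folds the arm's flank slope back on itself and builds edge
  ridges that read as blobs; the gradient-preserving rule continues ramps
  exactly, so a tilted plane passes through the band-pass untouched. The
  symmetric rule remains available as `border = "reflect"`.
* Odd grid sizes: decimation keeps ceil-half samples per axis and every
  level's exact shape is recorded, so expansion targets exact shapes and
  reconstruction is exact for any input size.
* Invalid cells (holes): infilled by normalized convolution before
  decomposition; the mask is reapplied afterwards, and patches treat masked
  cells as missing points.
* Degenerate patches (no positive heights, or fewer than 8 usable points)
  are dropped from the report with a warning rather than producing a
  diameter.
* Ties in the scale-space maxima are suppressed (strict maxima), making
  detection deterministic on synthetic plateaus; the whole pipeline is
  deterministic for a fixed input and configuration.
* The detector's scale ladder, thresholds and window factors, and all fit
  bounds, are package calibrations (exposed in `detection_config()` /
  `fit_config()`); published descriptions of this class of method do not
  state them.

## Known limitations

* The Laplacian-pyramid band-pass of a curved surface keeps a curvature
  pedestal; the axial-median correction removes it only insofar as it is
  constant along the arm. Strongly twisted or locally bulging anatomy would
  leave residuals that the per-patch quadratic baseline must absorb.
* Wheals larger than ~14 mm fall outside the default scale ladder, and
  wheals closer than ~8 mm to the scan border lose part of their window.
* The super-Gaussian and paraboloid families describe compact, single-
  peaked wheals; pseudopods are reduced to their dominant lobe.
* Adding the terminal pyramid level to a kept set can *decrease*
  reconstructed energy (the level below it subtracts the expanded residual
  by construction), so band energies are monotone only over detail-level
  additions — worth knowing when experimenting with `keep_levels`.

## Problem sizes used in the test suite

The bundled tests run the full pipeline on 900 x 320 px phantoms (the
default), the detector benchmark on 200 phantoms of 600 x 320 px, the cap
analog on 7 placements of 6 caps at 0.1 mm pitch, and the re-posing study
on 5 poses of a 6-wheal phantom; these sizes exercise every code path while
keeping a full run in the minutes range on one core.
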