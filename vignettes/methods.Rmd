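---
title: "Quantifying intraocular gas tamponade on simulated MRI: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intraocular gas tamponade on simulated MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

After vitrectomy with gas tamponade, an SF6 bubble floats in the vitreous
cavity and must press against the retinal breaks. On T2-weighted sagittal
MRI, intraocular fluid is bright and gas is dark, so for each eye and each
posture (prone or supine) one can measure three quantities on the images:

1. the **gas volume** as a percentage of the vitreous cavity, from per-slice
   planimetry integrated across the stack;
2. the **supraduction angle** between the pupillary axis and the vertical
   (eyes roll upward under closed lids — Bell's phenomenon — so the angle is
   generally positive even in a prone patient);
3. the **gas contact rate** of four retinal sectors on one mid-sagittal
   slice: superior/inferior times anterior/posterior, with the anterior
   sector running from the equator to the ora serrata and the posterior
   sector from the posterior pole to the equator.

This package reproduces that pipeline end to end and validates it against a
synthetic phantom whose geometry is known in closed form.

## Geometric model

The vitreous cavity is a perfect sphere. Sphericity is a modelling choice,
not an anatomical fact, but it is what makes closed forms possible, and eyes
with strongly aspheric globes (staphyloma) are outside the intended scope.
The default cavity radius is derived from the biometric axial length as
`R = (AL - 1.6 mm) / 2`; the 1.6 mm allowance absorbs the cornea and
anterior chamber, which are not part of the vitreous cavity in a
pseudophakic, vitrectomised eye. The allowance is a configurable parameter
of `eye_model()`.

A bubble filling the fraction `f` of the cavity floats against gravity and
is bounded below by a **flat meniscus**: the bubble is centimetres across
while the capillary length of an aqueous interface is about 2.7 mm, so
gravity dominates surface tension and interface curvature is negligible at
the pixel sizes involved. The gas then occupies a spherical cap of height
`h` solving `h^2 (3R - h) = 4 f R^3`; `cap_height_from_fraction()` solves
this cubic in closed trigonometric form, accurate to machine precision, and
`fraction_from_cap_height()` is its exact inverse.

On the mid-sagittal circle the retinal point at eye-frame angle `phi`
(0 at the corneal pole, positive superiorly) has height
`w = ±R cos(phi + theta)` with `theta` the supraduction angle and the sign
set by posture, so the gas-contact set is a single arc of half-width
`A = acos(1 - h/R)`. `analytic_contact_rates()` computes each sector's rate
as an exact circular-arc overlap; points exactly on the meniscus count as
contact (a measure-zero convention, fixed for determinism).

Two symmetry consequences are used as tests: rates are non-decreasing in
`f`, and at `f = 0.5` with no supraduction, reflecting the eye through the
horizontal plane maps the supine gas cap onto the prone fluid, so per-sector
supine and prone rates sum to exactly 100%.

## The phantom and what it does (not) emulate

`render_stack()` draws the scene the segmentation has to cope with: a
bright fluid region (intensity 200) and dark gas (20) inside the cavity
sphere, a thin darker scleral shell (60, 1.2 mm), dark background air (20),
and a schematic anterior segment — a 3 mm shell anterior to the cavity
within the limbal cone, carrying dark iris-margin and lens lines. The
anterior schematic sits strictly outside the cavity sphere so that it can
provide anterior-chamber-angle landmarks without perturbing the cavity
itself. Motion-robust acquisition is emulated only as Gaussian blur
(sigma 0.7 px) after additive Gaussian noise (default SD 5 on the 0–255
scale, a mid-range T2 contrast-to-noise); there is no k-space simulation,
no bias field, no ghosting. Tissue boundaries are anti-aliased by 4 x 4
subpixel supersampling, which also yields partial-volume-weighted
ground-truth areas.

Default acquisition geometry: 140 mm field of view, 320 x 320 matrix
(0.4375 mm pixels), 3.0 mm slices with 0.5 mm gap. The stack is centred on
the eye with the middle slice through the eye's centre.

Passing tests on this phantom therefore shows that the *measurement
pipeline* is unbiased under the stated intensity model; it does not show
robustness to real-MRI artefacts, to non-spherical globes, or to
multi-bubble ("fish-egg") gas configurations, all of which are out of
scope.

## Segmentation choices

* **Thresholds.** One Otsu threshold separates bright fluid from everything
  dark; a second Otsu split *within the dark class* separates very dark
  gas/air from the intermediate sclera, so the scleral shell isolates
  intraocular gas from background air. Both thresholds are estimated from
  the pooled stack histogram restricted to a padded bounding box around the
  bright class: single slices can hold almost no fluid (the outermost
  slices of a large bubble), and without the box the huge dark background
  dominates the class statistics.
* **Regions.** The gas seed is the enclosed (non-border-touching) very-dark
  component after a small opening that severs one-pixel noise leaks through
  the shell; it is regrown to all sub-fluid-threshold pixels inside the
  cavity. If a slice holds no fluid at all, the "bright" class degenerates
  to the scleral shell; this is detected (the bright component encloses the
  gas) and the cavity is then the gas region alone.
* **Areas.** A binary pixel count is biased by up to half a pixel at every
  boundary, and because the meniscus chord sits at the same image rows in
  every slice the error accumulates coherently across the stack rather than
  averaging out. Areas are therefore refined by partial-volume unmixing: a
  two-pixel band at each boundary weights every pixel by its apparent
  membership, interpolating linearly between the adjacent pure-class
  intensities. The scleral plateau is estimated as an upper quantile of the
  shell ring because the thin shell is partial-volume diluted from both
  sides. With this, recovered gas volumes sit within about ±0.7 points of
  truth across the printed fill range; plain binary counting errs by 2–4.
* **Integration.** The gas-volume percent is the ratio of summed
  (spacing-weighted) gas to cavity areas — ratio of sums, not a mean of
  per-slice percents, because for uniform spacing it equals the volumetric
  ratio.

## Slice geometry choices

* **Contour.** The cavity contour is refined to sub-pixel accuracy: along
  each radial ray the wall is placed where the intensity crosses halfway
  between the local interior value (fluid, gas, or their blend near the
  meniscus) and the scleral plateau. Stretches where this criterion is
  degenerate (the blend lands on the plateau value, which happens at the
  meniscus–wall junction) or deviates from a robust circle fit by more
  than 0.15 mm are repaired by the fitted circle — legitimate here because
  the globe is spherical by model assumption. A circular running median and
  a light mean filter suppress radial jitter, which would otherwise inflate
  polyline arc lengths and drag every arc-walked landmark anteriorly.
* **Axis and centre.** The eye centre is an algebraic circle fit (refitted
  once on the refined contour); the pupillary axis runs from the centre
  through the midpoint of the two anterior-chamber-angle landmarks, which
  the phantom provides in its ground-truth sidecar (automatic angle
  detection from clinical images is not attempted). The superior/inferior
  split uses this axis, anchored to the eye rather than to gravity.
* **Landmarks.** The surgical limbus is the intersection of the
  perpendicular from the angle landmark with the contour; the ora serrata
  and equator lie 7 and 13.5 mm posterior to the limbus measured as *arc
  length along the globe surface* (the surgical "mm from limbus" usage),
  not as chords.
* **Contact.** An arc point is in contact when, within `tolerance_px` along
  the inward normal, the gas fraction of the local cavity content reaches
  `coverage_level`. Normalising the gas coverage map by the cavity coverage
  map undoes the dilution of wall cells that lie partly outside the globe.
  The default tolerance is 1.0 px (0.44 mm): it still exceeds any fluid
  film the segmentation could resolve at this pixel size, while a larger
  allowance systematically overshoots past the meniscus–wall junction on
  the short (6.5 mm) anterior sectors. The default `coverage_level` of 0.4
  sits slightly below one half because cells at an acute gas wedge never
  reach half coverage; the value was calibrated against the analytic oracle
  across the fill/angle/posture grid. With these defaults, pixel-measured
  rates track the closed-form rates within 3 percentage points on
  noise-free stacks and within about 5 at twice the default noise.
* **Supraduction.** The signed angle between the measured axis and the
  vertical, positive toward head-superior in both postures (the vertical
  reference flips with posture). Recovery on the phantom is within about
  0.2 degrees, dominated by the centre estimate.

## Statistics choices

The posture comparison uses the unpaired Mann–Whitney U test even though
prone and supine measurements are paired by eye, mirroring the original
analysis; `compare_postures()` reports the paired Wilcoxon signed-rank p
alongside as a methodological note. Both tests enumerate their exact null
distributions (all sign assignments, respectively all group labelings) with
mid-ranks for ties, up to n = 20; beyond that a tie-corrected normal
approximation with continuity correction is used, and both p-values are
always reported. Two-sided p doubles the smaller tail, capped at 1 — the
convention under which near-identical groups give p = 1, as the gas-volume
comparison does. Zero differences are dropped by default (Wilcoxon's
original rule); Pratt's rule is available behind a flag because the
convention of the original analysis software is not documented. For the
acuity comparison the exact two-sided p is 0.023 while the one-sided exact
p is 0.012; which variant a given software prints is not knowable from a
table, so both are reported and neither is asserted against.

Cohort summaries report mean ± SE (sample SD over the square root of the
non-missing count) and reproduce every printed table cell at printed
precision; the acceptance script rounds half-up after snapping float
accumulation error, which is how the printed tables round (e.g. a mean of
exactly 1.75 degrees prints as 1.8).

## Problem sizes and reproducibility

The bundled cohort is 8 eyes x 2 postures at the full default resolution
(320 x 320, 7 slices per stack); a complete closed-loop run takes on the
order of a minute. All randomness (noise) is seeded; identical seeds give
bit-identical stacks and byte-identical output tables. The per-scenario
seed folds the case number so every stack is distinct yet reproducible.

## Known limitations

* The spherical-cavity assumption is load-bearing for both the closed forms
  and the contour repair; strongly aspheric globes would need a different
  contour model.
* Contact is measured on one mid-sagittal slice, as in the clinical
  protocol; no 3D surface-coverage quantity is computed, and break
  positions by clock hour are outside the sagittal plane.
* Anterior-chamber-angle landmarks come from the phantom sidecar; the
  schematic detector problem (finding them in a real image) is not solved.
* The phantom cohort reproduces the *direction* of the posture effect on
  every sector, but the magnitudes of sector rates in real eyes depend on
  individual anatomy that the spherical phantom does not carry, so printed
  per-sector means are not quantitative targets.
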