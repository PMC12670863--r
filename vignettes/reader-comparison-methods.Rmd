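---
title: "Multilevel reader comparison for CMR contours: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel reader comparison for CMR contours: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Quantitative cardiovascular MR rests on contours drawn on images: left- and
right-ventricular endocardium and epicardium on short-axis cine stacks,
myocardium on T1/T2 maps, scar on late gadolinium enhancement, atria on
long-axis views. Two readers — two humans, a human and an AI, an expert and a
trainee — never draw identical contours, and the resulting differences
propagate into clinical parameters (volumes, masses, ejection fractions,
mapping values) that drive decisions. Quality assurance therefore needs three
linked levels of comparison:

1. **segmentation metrics** per slice (Dice overlap, Hausdorff distance,
   the milliliter impact of an area difference),
2. **clinical parameters** per case, and
3. **study statistics** across cases (bias, its 95% confidence interval,
   acceptability, outliers).

`cmrqa` implements all three levels plus the connective tissue: tolerance
ranges that turn a bias into an accept/reject verdict, outlier detection,
and *error tracing* — the exact decomposition of a parameter difference into
per-slice contour contributions so that a flagged case can be explained, not
just flagged.

# The statistical model

## Bias and its confidence interval

For a parameter $p$ and $n$ cases, the paired differences
$d_i = p^{(1)}_i - p^{(2)}_i$ (reader 1 minus reader 2 throughout) are
summarised by their mean $\bar d$, sample SD $s$ (with $n-1$ denominator)
and the normal-approximation 95% confidence interval

$$\bar d \pm 1.96\, s/\sqrt{n}.$$

We use the normal critical value 1.96 rather than a Student-$t$ quantile:
at the study sizes this framework targets ($n \ge 30$, typically
$n \approx 144$) the two are indistinguishable at the reported precision,
and the z-form reproduces the published reference intervals exactly.

## Tolerance ranges

A bias verdict needs a yardstick. The yardstick is *intrareader*
variability: one expert annotates at least 30 cases twice, and the spread
of those differences defines what "as good as the same reader on a
different day" means. `derive_tolerance_range()` offers two methods, and
records which one produced every range:

* `z95` (default): half-width $= 1.96 \cdot \mathrm{SD}$ of the intrareader
  differences — the large-sample 95% population interval;
* `ki-factor`: a two-sided normal tolerance interval with Howe's factor
  $k = z_{0.975}\sqrt{\nu(1+1/n)/\chi^2_{0.05,\nu}}$, $\nu = n-1$, which
  additionally guarantees 95% *confidence* in the 95% coverage and widens
  the interval at small $n$.

Tolerance ranges are symmetric about zero (an unbiased reader is the
ideal), not centered on the intrareader mean. A new reader's bias is
**acceptable** iff its entire 95% CI lies inside $[-hw, +hw]$; a case is an
**outlier** for a parameter iff its single-case difference exceeds the
half-width in absolute value. Both definitions are monotone in the
half-width, which the test suite checks as a property.

# Geometry and metrics

Contours are closed polygons in continuous pixel coordinates; physical
area follows from the anisotropic pixel spacing, and the inter-slice
distance is $D = \text{thickness} + \text{gap}$.

* **Areas and volumes** use the shoelace formula and Simpson
  slice-summation $V = \sum_s A_s \cdot D / 1000$ (ml). No inter-slice
  interpolation: slice summation is the standard short-axis convention and
  the only rule consistent with a per-slice milliliter decomposition.
* **Dice** is computed on exact polygon intersection areas via a
  polygon-clipping kernel, not on rasterised masks — resolution-independent
  and testable against closed forms (concentric disks of radii $r<R$ give
  $2r^2/(r^2+R^2)$). A rasterised-mask oracle (0.1 mm grid, an independent
  winding-number implementation) is kept in the test suite and must agree
  within 0.005. The myocardium is compared ring-versus-ring (epicardial
  polygon minus endocardial polygon, an even-odd region with a hole);
  fragmented segmentations are lists of polygons.
* **Hausdorff distance** is measured between boundary polylines (not
  filled regions), after scaling to millimetres, with boundaries densified
  to ≤ 0.1 mm segments; the distance function is 1-Lipschitz, so the
  densification bounds the error by 0.05 mm.
* **Inclusion rules.** A slice annotated by exactly one reader scores
  Dice 0; a slice annotated by neither is undefined and excluded from all
  averages (scoring empty-vs-empty as 1 would inflate agreement). Tables
  report both "all slices annotated by ≥ 1 reader" and "slices annotated
  by both" averages; the first is never larger than the second, a property
  quantified over generated cohorts.

## Cardiac position

Slices are classified basal / midventricular / apical per contour type and
phase, relative to a chosen reference reader: the smallest slice index the
reference segmented and everything above it is basal, the largest and
everything below apical, the rest midventricular. When the reference
segments a single slice the degenerate stack is classified basal (a
deterministic tie-break; the alternative long-axis-orientation definition
is out of scope). Positions are computed per contour type because LV and
RV extents genuinely differ.

## Clinical parameters

| parameter | rule |
|---|---|
| LVESV, LVEDV, RVESV, RVEDV, LVV | Simpson summation of endocardial areas |
| LVSV, RVSV / LVEF, RVEF | $EDV - ESV$ / $100\,SV/EDV$ |
| LVM, PAPMU | ring (or papillary) volume × 1.05 g/ml |
| SCARM, SCARF | scar area clipped to the myocardial ring, × 1.05 g/ml; fraction of LVM |
| GLOBAL_T1/T2 | mean of voxels whose centers fall in the ring |
| atrial areas / volumes | polygon area (cm²); monoplane ellipsoid $V = 8A^2/(3\pi L)$ |

Choices that the sources of this field leave open, decided here:

* **Myocardial density 1.05 g/ml** — the standard post-processing
  convention.
* **ES/ED are the stored phase labels**; no argmin/argmax search over
  phases (only annotated phases are stored).
* **Papillary muscles** live in dedicated `papmu` contours and are
  reported as separate masses; the cavity volume includes the papillary
  region (the common "smooth endocardial contour" convention).
* **Atrial long-axis length** for the ellipsoid is the contour's maximum
  caliper diameter (largest pairwise boundary distance). No annulus
  landmark is needed, it is reproducible, and for a circular contour it
  reduces the formula to the sphere volume — a consistency check in the
  tests. Published monoplane lengths measured annulus-to-roof may differ
  slightly; supplying an explicit length is supported.
* **Voxel membership is center-in-polygon** with no partial-volume erosion
  margin; margins are a reader behaviour, not a processing step.
* **Angular segments** (6 by default, single slice) partition ring voxels
  by angle about the epicardial centroid, starting at the ray through the
  reference point, counterclockwise in image coordinates. Voxels
  numerically on the starting ray are snapped into sector 1 (an explicit
  1e-9 radian guard), so the sectors always partition the ring exactly.
  The full 17-segment model is out of scope.

# Error tracing

For slice-additive parameters (volumes, masses) the per-slice contribution
$(A^{(1)}_s - A^{(2)}_s)\,D/1000$ sums *exactly* to the parameter
difference — conservation is asserted to float tolerance over random
phantom pairs. Stroke volumes decompose into an ED trace plus a negated ES
trace, still exact. Ejection fractions and scar fraction are not
slice-additive; they are decomposed to first order (derivatives evaluated
at the two readers' mean values) plus a single explicit `nonlinearity`
residual entry that restores exact conservation, keeping the audit trail
honest instead of hiding the remainder in the slice terms. Entries are
ranked by absolute contribution, so the first row of a trace is the slice
that caused the outlier.

# The phantom cohort generator

Patient data cannot ship with a package, so every pipeline stage is
exercised on synthetic two-reader phantom cohorts with analytic ground
truth:

* the LV is a stack of circles whose radius falls linearly from
  `base_radius` (30 mm) to 40% at the apex over `n_slices` (8) annotated
  slices, with an 8 mm wall; end systole scales radii by 0.65 (EF ≈ 58%);
  slices are 8 mm with a 2 mm gap, pixels 1.4 mm. The most basal image
  (index 0) is deliberately left unannotated so a perturbed reader can
  add an extra basal slice.
* the RV is the circular-segment crescent of a second disk sharing the
  septal wall (the epicardial circle is subtracted), papillary muscles are
  two 4 mm disks, scar is an annular wedge (held 0.25 mm inside the ring
  so polygon truth is exact under clipping), mapping slices carry a
  value map (myocardium 1000 ms, blood 1600 ms, surround 300 ms, noise SD
  30 ms) and a reference point on the septal epicardial boundary, and
  atria are ellipses on long-axis views.
* per-case anatomy varies: an overall log-normal size factor (CV 8%) and
  a per-case ES scale jitter (SD 0.02) emulate inter-patient spread, so
  cohort statistics have realistic between-case variance.

The second reader is a parameterized perturbation: per-vertex radial
Gaussian noise (iid, which leaves the polygon area unbiased — the expected
cross-term of independent adjacent radii vanishes), per-contour-type
systematic dilation in mm, omission of the most basal annotated contours,
addition of contours on the unannotated basal image, fragmentation into
two polygons, and a reference-point shift. Occasional self-crossings from
vertex noise on non-convex contours are resolved through the clipper with
slivers below 0.5 mm² discarded. Everything is deterministic given the
seed; cohort case seeds are `master seed + case index` and are recorded in
the output.

What the phantoms deliberately do **not** emulate: image intensities
beyond the mapping value fields, pathology other than scar wedges,
through-plane motion, or the irregular shapes of real hearts. Passing
phantom tests therefore demonstrates the *correctness of the computations*
(metrics, parameters, statistics, traces, reports) under controlled truth,
not segmentation difficulty on real images.

# Numerical choices

* Polygons with ≥ 180 vertices keep circle-discretization error below
  0.02% in area (the inscribed-$k$-gon factor $\tfrac{k}{2\pi}\sin\tfrac{2\pi}{k}$),
  comfortably inside the 0.2% oracle bands used in the tests.
* Exact polygon booleans run through an integer-scaled clipper; identical
  contours can return Dice $1 - O(10^{-9})$, so equality assertions carry
  an epsilon.
* Hausdorff densification is 0.1 mm; metric oracles use a ±0.01–0.02 mm
  slack accordingly.
* Degenerate inputs: an epicardial contour smaller than the endocardial
  one clamps the ring to zero with a warning; ESV > EDV returns a negative
  SV with a warning; scar with zero LVM is an error; missing contours
  produce `NA` (distinct from 0) so absence is never silently scored.

The test suite runs its simulation-based properties at reduced phantom
sizes (4–5 slices, 96–180-gon contours, cohorts of 3–30 cases), which the
helper constructors in the suite state explicitly; the generator defaults
above describe the full-size phantom.

# Known limitations

* Dice/HD are 2-D per-slice metrics; no 3-D surface distances.
* Biplane atrial volumes and the 17-segment model are not implemented.
* Scar *detection* (thresholding) is out of scope — readers supply scar
  contours.
* Tolerance-range acceptability is statistical, not clinical: a bias that
  is acceptable against intrareader variability can still matter for a
  patient near a treatment threshold, and vice versa.
* Reports are HTML plus CSV and PNG side files; PDF rendering is left to
  external converters by design.
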