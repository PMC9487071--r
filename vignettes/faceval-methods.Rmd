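---
title: "faceval: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{faceval: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceval)
```

## The problem

Three-dimensional face models reconstructed from calibrated 2D photographs
(or any indirect capture) must be validated against a gold-standard optical
face scan before they can support clinical decisions. The accepted
methodology is: rigidly register the test model to the reference scan,
compute point-to-surface deviations over anatomically defined regions,
summarize them as RMSE against a 2 mm clinical-acceptability threshold,
decompose landmark errors along anatomical axes, compare standard
soft-tissue measurements with paired statistics, and report method error
(ICC, Bland–Altman). faceval implements that pipeline as reusable, tested
code, together with a synthetic data generator that provides the ground
truth real patient data cannot.

## Registration model

**Stage 1 (landmark alignment).** The proper rigid transform minimizing the
sum of squared distances between the four paired registration landmarks
(CanthusL, CanthusR, NoseTip, NasionSoft) is found in closed form by SVD of
the cross-covariance (Kabsch). The determinant correction excludes
reflections; collinear configurations are rejected. These four landmarks
are used because photo-based reconstructions are adjusted primarily at the
canthi, nose tip and nasion, so their error is small relative to plain
surfaces.

**Stage 2 (best fit).** Point-to-surface ICP: the test vertices are paired
with their *exact* closest points on the reference triangulation (not
nearest vertices), pairs farther than the rejection tolerance are dropped,
and a Kabsch update is estimated from the survivors. Correspondences are
point-to-surface because that matches the deviation semantics of the
clinical software the protocol comes from, and converges markedly better on
smooth faces.

Parameters and defaults:

| parameter | default | rationale |
|---|---|---|
| minimum iterations | 50 | protocol states "at least 50 iterations" |
| maximum iterations | 500 | termination guarantee |
| convergence threshold | 1e-3 mm on the RMS change | protocol's "precision to at least 0.1 mm" read as an upper bound; the default is stricter |
| rejection tolerance | 2 mm | protocol's "range of tolerance of 2 mm", applied from iteration 1 (the landmark seed is already sub-tolerance) |
| sampling fraction | 1.0 | protocol's "registration percentages to the maximum 100 %" |

Numerical choices: point-to-surface ICP carries no monotonicity guarantee,
so an update is accepted only if the recomputed RMS does not increase; the
logged RMS sequence is therefore non-increasing by construction, and the
convergence test is applied only after the minimum iteration count. Closest
triangle ties are broken toward the lowest triangle index for determinism.
The closest-point query is exact (per-triangle Voronoi-region walk in
compiled code) and accelerated by a uniform spatial grid with
expanding-shell search, so no approximation enters the pipeline.

## Anatomical frame, regions, deviations

The coordinate frame follows the soft-tissue Frankfort horizontal
convention: origin at the tragion midpoint, x along the tragion line
(subject's left positive), the plane through both tragions and the right
suborbital point as the x–y plane, z superior, y anterior (sign fixed by
the pronasale). The axis *semantics* (y = sagittal/anteroposterior,
z = vertical) follow the landmark-deviation reporting convention in which
the dominant reconstruction error is the sagittal y component.

Interactive segmentation is replaced by landmark-driven crops, which are
reproducible: the facial region spans frame-z from 5 mm below the
soft-tissue menton to 10 mm above the glabella and frame-x between the
tragions; the perioral region spans menton to subnasale vertically and
1.2× the cheilion half-width laterally. The perioral bounds are this
package's own definition (the source protocol never states one); the −5/+10
mm facial margins are pragmatic defaults. Faces are kept only when all
three vertices survive the crop.

Deviations are signed by the outward reference normal at the closest point
(outward orientation is normalized by flipping all faces when the mean
normal points toward the centroid — well-defined for the star-shaped/
height-field surfaces this package targets). RMSE is
`sqrt(mean(d²))` over the signed distances; since the distances enter
squared, the sign convention cannot change the value. Cohort summaries use
the t distribution for the 95 % CI (`mean ± t(0.975, n−1)·SD/√n`), matching
standard statistical-software defaults, not the normal approximation.
Color maps use a symmetric diverging blue–green–red palette over
[−limit, +limit], clamped beyond, exported as ASCII PLY with 8-bit
round-half-up quantization (OBJ has no portable vertex color).

## Soft-tissue measurements

All eight "height"/width measurements are 3D Euclidean inter-landmark
distances (Farkas-style convention; the measurement definitions name
landmark *pairs*, which supports direct distances — the alternative
vertical-projection reading of facial height N′–Gn′ is a known sensitivity
and is documented, not implemented). Angles are computed at the middle
landmark of each named triple via the clamped arccosine; the nasolabial
angle uses exactly the parenthesized triple Prn-Sn-Ls even though prose
descriptions sometimes reference the columella. Units are mm and decimal
degrees.

## 2D photo repositioning

The geometry (not the image resampling) of the repositioning protocol:
front photos are leveled so the lateral-canthus line is horizontal; the
vertical canthus-to-cheilion drop H1 is measured; the lateral photo is
rotated about its canthus until its drop equals H1. Raster convention
(y down) with screen-counterclockwise-positive angles is fixed explicitly,
since the original GUI workflow has no stated convention. The
two-solution ambiguity of the lateral rotation is resolved by anatomical
plausibility (cheilion below the canthus), then smallest magnitude. Which
canthus anchors H1 is a side parameter.

## Agreement statistics

- **Paired t**: textbook; identical inputs (zero-variance, zero-mean
  differences) are reported as t = 0, p = 1 with a degeneracy flag rather
  than NaN.
- **ICC**: the wording "2-way absolute agreement … on a mean of
  measurements" pins the McGraw–Wong form ICC(A,k) =
  (MSR − MSE) / (MSR + (MSC − MSE)/n). The CI is F-based: the
  single-measure interval with Satterthwaite denominator degrees of
  freedom, transformed to average measures by Spearman–Brown (the choice
  among software conventions; it reproduces the reference Python
  implementation to machine precision on test matrices). A constant matrix
  is returned as perfect agreement with a degenerate-CI flag.
- **Bland–Altman**: limits of agreement use the conventional 1.96
  multiplier; all CIs are t-based (bias: `t·SD/√n`; each limit:
  `t·SD·√(3/n)`), consistent with reporting limits and their CIs as
  separate columns.
- **Sample size**: smallest n such that the exact noncentral-t power of the
  two-sided paired t test reaches the target, iterating n upward. The
  normal approximation is deliberately not used: it returns a smaller n and
  does not reproduce the canonical worked result
  (δ = 0.42, σ = 0.68, α = 0.05, power 0.80 → n = 23, which
  `paired_sample_size()` returns and the acceptance suite asserts).

## The synthetic world

`generate_face()` builds a height field: anterior depth y = f(x, z) over an
elliptical outline (half-width 70 mm, half-height 90 mm), where f is an
elliptic-paraboloid dome (55 mm deep) plus Gaussian features (nose ridge
22 mm, brow 5 mm, lip rolls 2.5 mm, chin boss 6 mm). The dome is centered
2 mm above the tragion line so the pronasale and nasion rows are symmetric
about it. All 22 vocabulary landmarks are placed *analytically* on the
surface, not detected — eliminating landmark-detection confounds from
pipeline tests. The default grid (96 per side, ~7000 vertices inside the
outline) is the order of a decimated clinical scan.

`apply_deformation()` emulates reconstruction error with known ground
truth: Gaussian radial-basis bumps displace vertices along their area-
weighted normals, then a rigid perturbation is applied, then isotropic
noise along normals (default SD 0.05 mm, below a clinical scanner's 0.2 mm
stated accuracy). Landmarks ride the bump and rigid maps but are never
noised. The returned truth is the pre-rigid displacement magnitude — for
along-normal displacement within the surface's tubular neighborhood this
equals the point-to-surface distance a deviation analysis should recover,
which is why the RMSE-vs-truth acceptance check can be as tight as 2 %
(observed discretization error ≲ 0.1 %).

The default deformation tiles the face with 21 alternating-sign bumps:
3 mm peaks at forehead and cheeks (the regions photo-based reconstruction
recovers worst), 1.8 mm at the nasal alae and jawline, ~1 mm perioral.
Calibration note: a sparse forehead + cheek-only pattern with peaks capped
at 3 mm cannot push the facial-region RMSE into the reported 1.3–1.8 mm
band, because the facial crop is large and dilutes localized error; the
default therefore distributes moderate error across the face, consistent
with published color-coded deviation maps, and yields facial RMSE ≈ 1.6 mm
and perioral ≈ 0.9 mm after registration (facial > perioral, both < 2 mm).
Alternating signs are used so the best-fit registration cannot absorb the
deformation as a rigid motion.

What the generator does *not* emulate — and hence what a green test does
not establish: anatomical texture and curvature detail (the height field
has no nostrils, eyes or ears and a flat nasolabial profile, so angular
measurements take non-physiological values such as a ~174° nasolabial
angle — the tests assert their geometric invariances, not their clinical
plausibility); patient-to-patient shape variation beyond a few feature-
amplitude parameters; occlusion or missing data; spatially correlated
scanner noise. Statements about clinical accuracy of any real
reconstruction method remain outside what these tests can show.

## Determinism

Everything is seed-driven: the generator spec and deformation spec carry
seeds, `run_validation()` records the run seed in its report, and two runs
with the same config produce byte-identical `report.json` (fixed key order,
full-precision floats). The noise generator saves and restores the global
RNG state, so synthetic generation does not perturb a caller's random
stream.

## Known limitations

- Height-field faces only; the deviation sign convention assumes a surface
  whose outward orientation is star-shaped with respect to its centroid.
- Landmark-driven crops approximate, not reproduce, manual segmentation.
- `icp_refine` estimates rotation + translation only (no scale, no
  non-rigid component), by design: 2D photos are metrically repositioned
  upstream.
- The perioral region definition is this package's own; results for that
  region are comparable across faceval runs but not necessarily with other
  software's manual crops.
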