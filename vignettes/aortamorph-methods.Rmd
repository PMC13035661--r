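---
title: "Methods: aortic morphometry and the local false-lumen radiomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aortic morphometry and the local false-lumen radiomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

After surgical repair of a type A aortic dissection, a residual dissection of
the downstream aorta (RAD) often persists: the aortic wall is split into a
true lumen (TL), a perfused circulating false lumen (CFL), and, in many
patients, mural thrombus (TH). The clinical question is which patients will
undergo adverse aortic remodeling (growth beyond 5 mm/year, re-do surgery,
malperfusion, rupture) and might benefit from early endovascular treatment.

`aortamorph` implements the measurement side of this problem. Its input is a
3D integer label map of the aorta (codes for TL, CFL and TH; branches
excluded, wall included), with voxel spacing in millimetres. From it the
package derives:

- **Ao_length** (mm) — arc length of the aortic centerline, valve to
  aorto-iliac bifurcation;
- **D_max** (mm) — the maximal outer diameter measured on planes orthogonal
  to the centerline (the "double-oblique" convention), as the maximal Feret
  diameter of the cross-section;
- **component volumes** (mL) — `V_TL`, `V_CFL`, `V_TH`, their sum
  `Ao_Glo`, the global false lumen `FL_Glo = V_CFL + V_TH`, and the ratios
  `FL_Glo/Ao_Glo` and `FL_Glo/Ao_length`;
- **FL_Loc** (mL) — the false-lumen volume restricted to a 30-mm arc-length
  section (15 mm proximal, 15 mm distal) around the largest-diameter
  position; the measurement is repeated at the second-largest diameter at
  least 10 mm away and the larger of the two local volumes is retained;
- **evolution ("+") markers** — for paired scans at T1 and T2,
  `m+ = m(T1) + (m(T2) - m(T1)) * 365 / delta_days`, a linear extrapolation
  of the change to one year after T1;
- **prognostic statistics** — per-marker ROC AUC with a DeLong 95%
  confidence interval, the Youden-index operating point with sensitivity,
  specificity, PPV and NPV, the two-sample Kolmogorov–Smirnov distance,
  normality-gated group tests, and a univariate logistic likelihood-ratio
  test against a binary adverse-remodeling outcome.

Volumes are always voxel counts times the voxel volume in world units, never
voxel counts alone, so anisotropic spacing is handled uniformly and the
identities `Ao_Glo = V_TL + V_CFL + V_TH` and `FL_Glo = V_CFL + V_TH` hold
exactly on every input.

## Centerline extraction

No patient imaging ships with the package, and segmentation-model internals
are out of scope; the centerline is computed directly from the label map.
The design is a distance-penalised minimal path with cross-section
recentring:

1. **Extremity detection.** A double Dijkstra sweep on the 26-connected
   foreground voxel graph (edge costs are Euclidean step lengths in mm)
   finds the two geodesically most distant voxels. Ties break toward the
   lexicographically smallest voxel index, so the result is deterministic.
2. **Penalised path.** The path between the extremities is re-traced with
   per-voxel weight `1/(1 + d)^2`, where `d` is the Euclidean distance
   transform in mm (computed by the Felzenszwalb–Huttenlocher algorithm
   with per-axis spacing). This biases the path toward the medial axis.
3. **End trimming.** The raw path starts and ends on the boundary (the
   geodesic extremities sit on the end-cap rim); samples closer to the
   boundary than 90% of the median interior radius are trimmed from both
   ends, removing the oblique run-in.
4. **Cross-section recentring.** A minimal path through a wide lumen
   legitimately cuts corners even under penalisation. Each sample is
   therefore replaced by the centroid of the connected component containing
   it in the plane orthogonal to the local tangent; this restores the
   cross-sectional axis. Sections within about one radius of a cap are
   clipped by the cap and recentre with a bias, so after each recentring
   pass a guard zone at both ends is dropped and the curve is re-extended
   straight along the end tangents until it leaves the mask. Two
   extension/recentring rounds are run; the final extension restores the
   cap-to-cap span so the reported length covers the full vessel.
5. **Resampling.** The curve is smoothed with a 5-sample moving average and
   resampled at a uniform arc-length step (default 1 mm). Tangents are
   central differences of the resampled points.

An alternative design would be topological thinning of the voxel mask to a
skeleton followed by a longest-path search. On capped-tube geometry the
skeleton's longest path either stops about one radius short of each cap or
detours through the conical end sheets of the medial axis, so an
end-correction like step 4 is needed in either design; the penalised-path
formulation was chosen because all of its pieces (distance transform,
shortest path, plane resampling) are shared with the rest of the pipeline
and each is testable against closed forms.

On voxelised phantoms with analytic length (straight tubes, quarter arcs,
candy-cane arch-plus-limb curves, 0.5–2 mm spacing) the recovered length is
within 2% of truth for straight tubes and within 3% on strongly curved
arcs; the error saturates at a noise floor of roughly 0.1% set by smoothing
and end extension, so refining the spacing tightens a bound rather than
producing strictly monotone convergence (the volume measures, by contrast,
do converge monotonically on the phantom family).

The orientation (root-to-bifurcation versus reverse) is not identifiable
from the label map alone and is irrelevant downstream: all consumers use
absolute arc distances and window sums.

## Diameter profile and D_max

At every centerline sample the union mask is resampled on a square plane
orthogonal to the local tangent (trilinear interpolation of the binary
mask at 0.5 mm in-plane resolution, thresholded at 0.5; plane frames are
parallel-transported along the curve to avoid sudden flips). The connected
component containing the centerline point is kept — at high curvature or in
a candy-cane arch the plane may also cut the opposite limb, which must not
inflate the diameter — and its maximal Feret diameter (greatest pairwise
distance over the convex hull of component pixels) is recorded.

Samples within `end_guard` (default 10 mm) of either end are flagged
invalid rather than dropped: near an open end the plane cuts obliquely
through the cap and the Feret diameter is inflated. Flagged samples are
excluded from the D_max search and from FL_Loc candidate positions, but
their diameters remain available and the component volumes are unaffected.
The default plane extent is 120 mm (at least twice the largest clinically
plausible dissected-aorta diameter); if a section reaches the plane edge
the profile aborts with advice to enlarge the extent rather than silently
truncating.

## FL_Loc

The diameter profile yields `s1`, the position of the global maximum over
valid samples, and `s2`, the position of the largest diameter among valid
samples at least `min_separation` (default 10 mm) from `s1` — by
construction the second-largest eligible diameter, not necessarily a local
maximum. Diameter ties break toward the smaller arc length,
deterministically. Around each candidate a window of `section_length`
(default 30 mm) is clipped to the available centerline span without
re-centering, preserving the "around the position" semantics at the vessel
ends.

Every CFL and TH voxel is assigned to its nearest resampled centerline
point by Euclidean distance; the window volume is the sum of voxel volumes
over samples whose arc length falls inside the window. Nearest-point
assignment, rather than slabs between normal planes, cannot double-count
voxels at high curvature and partitions the false lumen exactly: summing
over any disjoint tiling of windows reproduces `FL_Glo` to floating-point
accuracy, which the test suite asserts. FL_Loc is the larger of the one or
two window volumes; it is monotone non-decreasing in the section length,
bounded by `FL_Glo`, and equals `FL_Glo` once the window covers the vessel.

One degenerate case deserves note: on a phantom whose diameter profile is
exactly flat, every sample ties for the maximum and the tie-break places
`s1` at the smallest valid arc length, where the window is clipped by the
vessel end. The uniform-tube proportionality oracle
(`window volume = FL_Glo * span / length`) is therefore exercised with an
interior window; real profiles have a unique peak and are unaffected.

## Evolution markers

The "+" marker linearly extrapolates the T1-to-T2 change to one year after
T1, with `year_length` configurable (365 days by default; 365.25 would
change results by under 0.1%). Intervals shorter than 30 days trigger a
warning — extrapolating a year from a few weeks amplifies measurement noise
— but are not refused, since the interval distribution is a property of the
cohort, not of the formula. Negative changes are deliberately not floored:
false-lumen volumes do shrink under favourable remodeling, and flooring
would bias the marker.

## Prognostic evaluation

- **ROC/AUC.** The classification rule is fixed as "positive if marker ≥
  threshold" (all markers here are adverse when large; a direction flag
  covers the opposite case). The AUC is the trapezoid area, computed as the
  midrank Mann–Whitney statistic with ties scored 0.5; the suite verifies
  equality with explicit pair counting to 1e-12 and with an independent ROC
  implementation.
- **Confidence intervals.** DeLong's placement-variance estimate with a
  Wald interval clipped to [0, 1], chosen over the bootstrap for
  determinism; a seeded percentile bootstrap is available behind a flag.
  When all values are tied the variance degenerates and the interval
  collapses to the AUC with a warning.
- **Operating point.** The threshold maximising Youden's J = Se + Sp − 1,
  ties broken toward the lowest threshold (the more sensitive operating
  point, matching the screening intent of a rule-out marker); PPV and NPV
  come from the 2×2 table at that threshold on the same cohort. The
  negative predictive value is labelled `pnv` in reports, following the
  clinical reporting convention for this marker family.
- **Group tests.** Student's t (paired or two-sample) when each sample has
  n ≥ 30 or passes Shapiro–Wilk at 0.05, otherwise
  Wilcoxon/Mann–Whitney; bounded scores such as Dice coefficients should
  use the `force_nonparametric` flag. The test used is returned as
  metadata.
- **Likelihood-ratio test.** Univariate logistic regression (IRLS via
  `glm`, convergence tightened to 1e-10) against the intercept-only model;
  2×Δloglik is referred to chi-square with 1 df. Perfect separation makes
  the statistic unbounded and is reported as an explicit error rather than
  a large number.

## Synthetic data

Two generators make every stage testable without patient data; their
defaults are the study conditions, not tuning knobs.

**Voxel phantoms.** A parametric tube with radius profile
`r(s) = r0 + A exp(-(s - s0)^2 / (2 w^2))` along a straight, quarter-arc,
or candy-cane (semicircular arch joined C¹ to a straight limb) centerline
is voxelised by assigning each voxel to its nearest densely-sampled curve
point and including it when its distance is at most `r(s)`; flat caps
terminate the ends. Each cross-section is split by a plane through the
local axis so the false lumen occupies `fl_fraction` of the area, with an
angular sub-sector of `th_fraction` of the false lumen labelled thrombus —
the simplest geometry in which TL, CFL and TH are all non-empty and
contiguous. Default geometry (r0 = 15 mm, length 100 mm, 0.5 mm isotropic
spacing, bulge amplitude 5 mm and width 10 mm when present) matches the
calibre of a dissected thoracic aorta. All reference measures come from
adaptive quadrature of `pi r(s)^2` and closed forms (`D_max = 2 max r`,
windowed integrals for FL_Loc), so measured-versus-analytic comparisons
have a genuinely independent oracle. Phantoms do not emulate CT intensity,
noise, wall irregularity, intimal-flap geometry or multichannel
dissections; passing phantom tests demonstrates geometric correctness of
the measurement pipeline, not segmentation robustness on real CTA.

**Cohorts.** The two validation cohorts are simulated from their printed
group summaries: event and event-free marker values drawn as Gaussians
with the published means and SDs at the published group sizes (internal
cohort: 39 events / 44 event-free; external: 33 / 46). Normality is the
minimal assumption available from summary statistics and makes the
population AUC available in closed form,
`pnorm((mu_e - mu_n) / sqrt(sd_e^2 + sd_n^2))`; real volume markers are
right-skewed, which is why the external-cohort reconstruction is held to a
looser tolerance. Markers are drawn independently of one another, so
joint statistics across markers (e.g. differences between correlated
AUCs) are outside what the simulator can reproduce. The paired-cohort
generator adds per-group annual change and a per-patient interval
(194 ± 77 days, truncated above 30) so the annualise-then-evaluate chain
can be tested end to end.

## Problem sizes and runtime choices

The reference phantoms used by the validation suite are 100-mm tubes at
0.5 mm isotropic spacing (about 10⁶ voxels; centerline plus profile in a
few seconds each) with coarser 1–2 mm variants for invariance checks; the
statistical calibrations use 500 replicates at n = 200 for type-I error
and 10,000 replicates for the binormal AUC reconstructions, where the
Monte-Carlo standard error of the mean (≈ 0.0006) is comfortably below
the comparison tolerances. These sizes were chosen so the full suite runs
in well under a minute while keeping every tolerance dominated by method
error, not simulation noise.

## Known limitations

- The centerline assumes a single connected, roughly tubular lumen; it has
  no branch handling (branches are assumed excluded from the labels) and
  no special treatment of stent-graft artefacts.
- D_max uses the outer contour of the union mask; per-segment breakdowns
  (arch versus descending) and entry-tear measurements are not computed.
- The evaluation is univariate per marker; no multivariable model, no
  time-to-event analysis.
- Phantom validation bounds discretisation error, not anatomical realism;
  accuracy on real segmentations depends on segmentation quality upstream.
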