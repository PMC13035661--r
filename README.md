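# aortamorph

Morphometry and prognostic evaluation of residual aortic dissection from
3D label segmentations.

After surgical repair of a type A aortic dissection, many patients keep a
residual dissection of the downstream aorta: the wall is split into a true
lumen (TL), a circulating false lumen (CFL) and, often, mural thrombus
(TH). Identifying the patients headed for adverse aortic remodeling
(growth > 5 mm/year, re-do surgery, malperfusion, rupture) from a baseline
CT segmentation is the clinical problem this package serves. It is aimed at
imaging researchers who already have label maps (from manual segmentation
or a segmentation model) and need reproducible measurements and marker
evaluation downstream of them.

## What it computes

Given a NIfTI label volume (codes for TL / CFL / TH, spacing in mm),
`aortamorph` derives:

- **Ao_length** — centerline arc length (mm), from a distance-penalised
  minimal path with cross-section recentring;
- **D_max** — maximal aortic diameter (mm) as the largest maximal Feret
  diameter over cross-sections orthogonal to the centerline
  (double-oblique convention);
- **volumes** (mL) — V_TL, V_CFL, V_TH, their sum Ao_Glo, the global false
  lumen FL_Glo = V_CFL + V_TH, and the ratios FL_Glo/Ao_Glo and
  FL_Glo/Ao_length;
- **FL_Loc** (mL) — the local false-lumen radiomarker: false-lumen volume
  inside a 30-mm arc-length section (15 mm proximal/distal) around the
  largest-diameter position, repeated at the second-largest diameter at
  least 10 mm away, keeping the larger of the two volumes;
- **evolution markers** — `m+ = m(T1) + (m(T2) − m(T1)) · 365/Δdays`, the
  one-year linear extrapolation for paired scans;
- **prognostic statistics** per marker against a binary outcome: trapezoid
  (midrank) ROC AUC with DeLong 95% CI, Youden-index threshold with
  Se/Sp/PPV/NPV, two-sample Kolmogorov–Smirnov distance,
  normality-gated group tests, univariate logistic likelihood-ratio test.

A synthetic-data module generates voxelised dissected-aorta phantoms with
closed-form ground truth (tube geometry with Gaussian bulges, straight /
quarter-arc / candy-cane centerlines, configurable false-lumen and
thrombus fractions) and simulated two-group marker cohorts, so the whole
pipeline is testable without patient data.

## Worked example

Measure a bulged, half-dissected tube phantom whose analytic truth is
known, then evaluate simulated cohort markers:

```r
library(aortamorph)

spec <- phantom_spec("straight", length = 100, r0 = 15,
                     bulge = list(amplitude = 5, center = 50, width = 10),
                     fl_fraction = 0.5, spacing = 0.5)
ph <- voxelize_phantom(spec)
m <- measure_aorta(ph$volume, sweep = c(10, 15, 30, 50))
dplyr::select(m, d_max, d_max_position, ao_length, ao_glo, fl_glo, fl_loc)
#> # A tibble: 1 × 6
#>   d_max d_max_position ao_length ao_glo fl_glo fl_loc
#>   <dbl>          <dbl>     <dbl>  <dbl>  <dbl>  <dbl>
#> 1    40           50.1      100.   84.2   42.1   16.1
```

The measured peak diameter (40 mm at arc length 50.1 mm) and volumes match
the phantom's closed forms (`ph$analytic`: D_max 40 at s = 50, Ao_Glo
83.89 mL, FL_Glo 41.94 mL, FL_Loc 16.39 mL): the 30-mm window around the
bulge holds 16.1 mL of the 42.1 mL false lumen.

```r
cp <- remodeling_cohort_params("center1")
cohort <- simulate_marker_cohort(cp$params, cp$n_event, cp$n_nonevent, seed = 1)
report <- evaluate_markers(cohort, c("d_max", "fl_glo", "fl_loc"))
dplyr::select(report, marker, auc, auc_ci_low, auc_ci_high, threshold, se, sp, ks)
#> # A tibble: 3 × 8
#>   marker   auc auc_ci_low auc_ci_high threshold    se    sp    ks
#>   <chr>  <dbl>      <dbl>       <dbl>     <dbl> <dbl> <dbl> <dbl>
#> 1 d_max  0.752      0.642       0.862      43.5 0.667 0.841 0.508
#> 2 fl_glo 0.848      0.765       0.931     127.  0.897 0.727 0.625
#> 3 fl_loc 0.858      0.777       0.939      18.1 0.744 0.864 0.607
```

Each row reports one marker against the adverse-remodeling outcome on one
simulated 83-patient cohort: the AUC with its DeLong interval, the
Youden-index threshold in the marker's units with the sensitivity and
specificity achieved there, and the KS distance between the event and
event-free distributions. On this draw the local false-lumen volume
separates the groups best, the expected ordering under the cohort's
group-summary parameters.

A thin command-line front end with `measure`, `phantom`, `cohort`,
`annualize` and `evaluate` subcommands is installed at
`inst/cli/aortamorph.R`.

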