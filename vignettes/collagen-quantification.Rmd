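---
title: "Quantifying fibrillar collagen and ECM in stained prostate histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrillar collagen and ECM in stained prostate histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagenquant)
```

## The measurement problem

Benign prostatic hyperplasia (BPH) studies ask whether fibrosis — collagen
deposited into the extracellular matrix (ECM) — distinguishes hyperplastic
nodules from normal glandular prostate and predicts lower urinary tract
symptoms. Three complementary readouts are used on archival tissue:

* **Picrosirius red (PSR) under circularly polarized light.** Birefringence
  is highly specific for fibrillar collagen, and its colour encodes fibre
  thickness: thin fibrils appear green, shifting through yellow and orange
  to red for the thickest bundles. Quantification reduces to classifying
  every tissue pixel into one of four hue bins.
* **Masson's trichrome (MTC).** ECM stains blue against red/pink cytoplasm;
  the score is mean blue intensity per tissue area.
* **Second harmonic generation (SHG).** A label-free nonlinear signal from
  thick (type I) collagen; stacks of 12–15 optical sections per core are
  flattened to a maximum-intensity z-projection (MIP) and scored as mean
  gray intensity.

`collagenquant` implements all three readouts plus the statistics used to
compare groups and associate collagen metrics with clinical covariates, and
a seeded synthetic-image generator that drives exact, zero-tolerance tests
of the measurement code.

## The colour model

All thresholds live in 8-bit hue/saturation/brightness (HSB) space, the
scale on which interactive threshold tools display their bounds. Hue is the
angle on the colour wheel scaled by 255/360 and rounded down, so pure blue
(240°) sits at hue 170; saturation is `(max − min)/max` scaled to \[0, 255\];
brightness is the maximum channel. Achromatic pixels get hue 0 and
saturation 0.

The shipped bins are:

| bin    | hue    | saturation | brightness |
|--------|--------|------------|------------|
| red    | 1–13   | 10–255     | 20–255     |
| orange | 14–25  | 10–255     | 20–255     |
| yellow | 26–52  | 10–255     | 20–255     |
| green  | 53–110 | 10–255     | 20–255     |
| blue (MTC ECM) | 121–179 | 20–255 | 10–255 |

Every bound is inclusive on every axis; that convention makes bin
disjointness checkable and matches threshold-tool behaviour. The hue
thresholds only make sense on the 8-bit wheel (blue at 121–179 would be
nonsense in degrees). Two deliberate edge decisions:

* **No red wraparound.** Deep-red birefringence with hue above 230 is left
  unclassified, because the red bin as printed starts at hue 1 and no
  wraparound is stated. Users who disagree can widen the red bin in the
  YAML config (`system.file("extdata", "default-config.yaml",
  package = "collagenquant")` is a template).
* Hue 0 (pure red *and* all achromatic pixels) is unclassified; the bins
  start at hue 1, which conveniently excludes gray pixels whose hue is 0 by
  convention.

```{r bins}
psr_bins()$orange
classify_hue(c(5, 14, 53, 111), s = 100, b = 100)
```

## Preprocessing: background and ROI

Two manual steps in the original workflow are replaced by deterministic
rules, with explicit escape hatches:

* **Background correction.** Polarized-light frames carry a small uniform
  colour cast. `estimate_background()` takes the per-channel median of the
  darkest `dark_quantile` fraction of pixels (default 0.25, ranked by HSB
  brightness; ties broken by row-major order under a stable sort) and
  `correct_background()` subtracts it, clamped at zero. The interactive
  plugin originally used for this step has no published parameters, so the
  dark-quantile rule is a declared replacement chosen for reproducibility,
  not a reconstruction of the original settings. Re-estimating on corrected
  output returns zero offsets, so the correction is idempotent.
* **Region of interest.** Total collagen content is defined against tissue
  pixels only — empty space and glandular lumens are subtracted. Lumens are
  dark under polarization and so invisible in the polarized frame; the ROI
  is therefore built from the pixel-aligned brightfield partner:
  `tissue_mask()` excludes near-white pixels (brightness ≥ `white_cut`
  = 230 **and** saturation ≤ `min_sat` = 25). Raising `white_cut` can only
  grow the mask (monotonicity is tested). A user-supplied mask file
  (single-channel PNG/TIFF, nonzero = inside) overrides the automatic rule.
  There is no image registration: partner frames are assumed pixel-aligned,
  as they are when both modes are captured on the same stage position.

## PSR quantification

`quantify_birefringence()` counts ROI pixels per bin and reports both
denominators that appear in the study design:

* `total_fraction` = birefringent pixels / ROI size (total collagen
  content);
* `prop_*` = bin count / total birefringent pixels (fibre-thickness
  distribution *within* collagen).

Images with zero birefringent pixels get `NA` proportions — flagged
undefined and excluded from proportion statistics rather than letting 0/0
silently bias a group mean; their `total_fraction` of 0 is kept.

Replicate fields (up to three per patient) are averaged unweighted by
`average_replicates()`. Per-colour proportions are then normalized by
`normalize_to_reference()`: each sample's proportion is divided by the
reference group's mean, pinning the reference group's normalized mean at
exactly 1 — the "1.000 ± SEM" convention in which such results are
reported. The reference label is always an explicit argument; the package
never infers it. Whether aggregation happens at the core or the patient
level is a config switch (`aggregation`), since tissue-microarray designs
with duplicate cores can be read either way.

## MTC and SHG scoring

"Mean blue intensity per tissue area" is operationalized as the sum of the
HSB brightness of blue-thresholded pixels divided by the tissue pixel
count. The exact intensity definition behind published values is not
stated anywhere we can check, so this choice is declared rather than
inferred; it reproduces the printed 0–255-scale magnitudes (group means
near 5–6), and the plain area fraction is emitted alongside
(`blue_area_fraction`) for users who prefer an unweighted measure.

SHG stacks are flattened with `max_project()` (elementwise maximum, so the
projection dominates every slice pointwise) and scored with `mean_gray()`.
The default scoring region is the whole projected field, matching per-core
scoring without masking; an optional mask supports excluding empty core
margins, since it is unknowable from the published record whether margins
were excluded.

## Statistics

All group comparisons use the **pooled-variance** (Student's) two-sample
t-test with df = n1 + n2 − 2 and two-sided p. The pooled form is chosen
because the reported analyses are Student's t-tests and the printed SHG
p-value is consistent with pooling at two decimals. Two routes exist and
are proven equivalent to 1e-12 in the tests:

* `ttest_pooled(x, y)` on raw values;
* `ttest_from_summary(m1, sem1, n1, m2, sem2, n2)` reconstructing
  `sd = sem * sqrt(n)` — this is what lets published mean/SEM/n triplets be
  re-analysed without raw data.

```{r ttest}
# SHG collagen score, hyperplastic nodules (n = 11) vs normal tissue (n = 10)
tidy(ttest_from_summary(62.52, 2.74, 11, 51.77, 3.49, 10))
```

Degenerate inputs are defined, not errors: zero pooled variance with equal
means gives p = 1 (equal printed means therefore give p = 1.00 exactly);
zero pooled variance with unequal means gives p = 0 flagged `degenerate`.

Clinical associations are univariate: `linreg()` (ordinary least squares
via `lm()`, slope ± SE, R², p from t = slope/SE at df = n − 2) per
continuous covariate and a pooled t-test per treatment flag, assembled by
`run_association_battery()` with listwise missing-data handling per
covariate — each table row may use a different n, as in retrospective
chart-review tables. No multiplicity adjustment is applied by default,
matching the univariate reporting convention; `adjust = "BH"` is available.
Covariates are not log-transformed by default (no transformation is stated
for the published regressions, including PSA, which a sceptical analyst
might have logged).

## The synthetic generator

The generators fabricate every input the pipeline consumes, with exact
ground truth, so that correctness tests can demand **zero tolerance**:

* Painted HSB colours sit ≥ 2 units inside their bin boundaries, so
  RGB↔HSB quantization (±1 unit) cannot move a pixel across a bin edge.
* The polarized background is a uniform offset (default (10, 5, 12));
  background estimation recovers it exactly and subtraction restores the
  painted colours bit-exactly. Fibres are polyline strokes of integer
  width; strokes only paint unclaimed tissue pixels, so bin ownership is
  unambiguous and per-bin counts are exact by construction (the last stroke
  is trimmed to hit the target count).
* Trichrome ECM pixels are painted at a fixed brightness (default 200), so
  the expected mean blue intensity is exactly
  `ecm_fraction × blue_brightness`.
* SHG fibres get a Gaussian intensity falloff (σ = 1.5 slices) around a
  focal slice in a 12–15-slice stack; the generator records the exact
  elementwise-maximum projection and its mean.
* Every generator is a pure function of `(seed, params)` — identical seeds
  give byte-identical output.

Defaults were set once from the published summary statistics and are not
tuning knobs: total birefringent fraction 0.53 (the reported group mean of
52.9%), bin proportions 10/15/40/35% for red/orange/yellow/green,
between-patient coefficients of variation 0.47/0.31/0.16/0.23 (the values
implied by the reported normalized SEMs at n = 24) and total-fraction CV
0.21; cohort covariates match the reported medians, IQRs and availability
fractions (log-normal PSA and post-void residuals, near-normal age and
symptom index). `gen_cohort()` generates its collagen metric as a linear
function of chosen covariates plus Gaussian noise with all slopes
defaulting to 0, the reported null.

What the fixtures deliberately do **not** emulate: polarization optics,
point-spread functions, stain variability, chromatic noise on fibres, or
tissue texture. Passing the exact-recovery tests shows the measurement
code is correct; it does not show that the thresholds segment real
micrographs well — that validation requires real stained tissue.

## End-to-end runs

`run_tma_comparison()` executes manifest → preprocess → quantify →
aggregate → normalize → pooled t-tests per metric, writes tidy CSVs and a
`params.yaml` log capturing every threshold, the reference group, the seed
and the package version — enough to reproduce a run byte-identically.
Unreadable files become rows in `$errors`; the run continues.
`run_clinical_association()` joins per-patient quantification to a clinical
CSV and emits the association table (covariate, n, median \[IQR\],
slope ± SEM, R², p).

```{r e2e}
dir <- tempfile()
man <- simulate_psr_study(dir, seed = 1,
                          groups = c(normal = 8L, bph = 6L), size = 48)
cfg <- default_config(); cfg$reference_group <- "normal"
cmp <- run_tma_comparison(man, cfg)
tidy(cmp)
```

## Problem sizes, numerics, limitations

The validation suite runs at deliberately modest scale, chosen as the
smallest sizes at which each property is meaningful: 48–64 px synthetic
frames (exactness does not depend on frame size), 100 seeded fixtures for
ground-truth recovery, 10,000 simulated null pairs at n = 20/group for
t-test calibration (rejection 5% ± 1% at α = 0.05), 500 cohorts of n = 100
for slope-coverage, and 100 seeds of a 24-vs-48-patient study with a +25%
orange-proportion shift for end-to-end power of the group comparison.

Known limitations:

* HSB box thresholds only — no colour deconvolution or stain unmixing, no
  fibre tracing or orientation analysis; colour bins are the only
  fibre-thickness proxy.
* No registration between brightfield and polarized frames.
* The MTC intensity definition and the SHG margin-exclusion question are
  declared operationalizations (both alternatives are exposed).
* Statistical layer is univariate by design; no survival, mixed-effects or
  multivariable models.
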