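# collagenquant

Quantification of fibrillar collagen and extracellular matrix (ECM) in
stained prostate histology, with the statistics used to compare tissue
groups and associate collagen content with clinical parameters of benign
prostatic hyperplasia (BPH) and lower urinary tract symptoms.

## Who this is for

Researchers scoring archival tissue (tissue-microarray cores or full
surgical sections) with any of three standard collagen readouts:

- **Picrosirius red (PSR) birefringence** under circularly polarized light —
  specific for fibrillar collagen, with colour encoding fibre thickness
  (green = thin fibrils → yellow → orange → red = thick bundles);
- **Masson's trichrome (MTC)** — ECM stains blue against red/pink cytoplasm;
- **Second harmonic generation (SHG)** — label-free signal from thick
  type I collagen, acquired as stacks of optical sections.

## The method

All colour thresholds are inclusive boxes in 8-bit
hue/saturation/brightness (HSB) space (hue = angle × 255/360, floored).
Birefringent pixels inside the tissue region of interest (ROI) are
classified into four hue bins — red H 1–13, orange H 14–25, yellow H 26–52,
green H 53–110 (all S 10–255, B 20–255). Two quantities follow:

- total collagen fraction = birefringent pixels / ROI size, where the ROI
  excludes empty and glandular (lumen) space via near-white exclusion on
  the pixel-aligned brightfield partner image;
- per-colour proportions = bin count / birefringent pixels, normalized so
  the reference group's mean is exactly 1.

MTC ECM content is scored as mean blue intensity per tissue area (blue box
H 121–179, S 20–255, B 10–255); SHG stacks are flattened to a
maximum-intensity z-projection and scored as mean gray intensity.

Group comparisons use the pooled (Student's) two-sample t-test, df =
n₁+n₂−2, two-sided — computable either from raw values or directly from
published mean/SEM/n triplets (`ttest_from_summary()`, sd = SEM·√n).
Clinical associations are univariate ordinary least squares (slope ± SEM,
R², p) per covariate and pooled t-tests per treatment flag, with listwise
missing-data handling and no multiplicity adjustment by default.

A seeded synthetic generator fabricates every input type — polarized/
brightfield PSR pairs, trichrome images, SHG stacks, clinical cohorts —
with exact painted ground truth, so the measurement code is tested at zero
tolerance.

## Worked example

Re-analysing a published SHG comparison from its printed summary
statistics — hyperplastic nodules 62.52 ± 2.74 (n = 11) vs normal prostate
51.77 ± 3.49 (n = 10):

```r
library(collagenquant)
tidy(ttest_from_summary(62.52, 2.74, 11, 51.77, 3.49, 10))
#> # A tibble: 1 × 8
#>   estimate estimate1 estimate2 statistic    df p.value method       degenerate
#>      <dbl>     <dbl>     <dbl>     <dbl> <dbl>   <dbl> <chr>        <lgl>
#> 1     10.8      62.5      51.8      2.45    19  0.0243 summary sta… FALSE
```

p = 0.0243 — the collagen signal is significantly higher in the nodules
(rounds to the printed 0.02).

A full synthetic study, end to end:

```r
dir <- tempfile()
man <- simulate_psr_study(dir, seed = 11,
                          groups = c(untreated = 24L, treated = 48L),
                          prop_shift = list(treated = c(orange = 1.25)))
cfg <- default_config(); cfg$reference_group <- "untreated"
cmp <- run_tma_comparison(man, cfg)
tidy(cmp)
#> # A tibble: 5 × 10
#>   metric          mean_ref sem_ref mean_other sem_other n_ref n_other      t    df       p
#> 1 total_fraction     0.560  0.0264      0.503    0.0134    24      48 -2.15     70 0.0354
#> 2 norm_prop_red      1      0.0886      0.916    0.0526    24      48 -0.863    70 0.391
#> 3 norm_prop_orange   1      0.0593      1.24     0.0573    24      48  2.68     70 0.00925
#> 4 norm_prop_yellow   1      0.0254      0.952    0.0172    24      48 -1.60     70 0.113
#> 5 norm_prop_green    1      0.0299      0.972    0.0265    24      48 -0.639    70 0.525
```

The planted +25% orange-proportion shift (thicker collagen bundles in the
treated group) is detected at p = 0.009; the reference group's normalized
means sit at exactly 1. `autoplot(cmp)` draws the grouped bar chart;
`run_clinical_association()` produces the covariate table.

## Layout

- `R/` — colour model, preprocessing/ROI, PSR/MTC/SHG quantification,
  statistics, synthetic generators, IO/config, pipelines, tidiers, plots
- `vignettes/collagen-quantification.Rmd` — methods: model, parameters,
  numerical choices, generator design, limitations
- `inst/extdata/default-config.yaml` — all thresholds, overridable per run
- `tests/testthat/` — unit, property and acceptance suites
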