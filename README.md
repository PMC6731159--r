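# ihc4score

Prognostic-information comparison for luminal (hormone-receptor-positive)
breast cancer: continuous immunohistochemical scores versus categorical
surrogate subtypes.

## Problem and audience

Luminal breast cancer is routinely subtyped as **A-like** (ER+ and PR+,
HER2−, image-analysis KI67 ≤ 12%) or **B-like** (ER+ and/or PR+, with
KI67 > 12% or HER2+) to guide chemotherapy decisions.  Dichotomising the
four markers throws information away.  This package — aimed at
biostatisticians and cancer epidemiologists — implements the quantitative
alternative and the machinery to compare the two on 10-year breast
cancer-specific survival:

* the **IHC4 score**,
  `94.7 × {−0.100·ER10 − 0.079·PR10 + 0.586·HER2 + 0.240·ln(1 + 10·KI67)}`,
  from image-analysis marker percentages (`compute_ihc4()`), with per-core
  to patient-level averaging (`aggregate_cores()`);
* the clinical treatment **C-score** and the **PREDICT (ER+)** linear
  predictor over age, tumour size, nodal count and grade
  (`compute_c_score()`, `compute_predict_score()`);
* subtype classification, per-SD standardisation, quartiles and the
  mean + 1 SD high/low IHC4 split (`classify_subtype()`,
  `standardize_per_sd()`, `assign_quartiles()`,
  `dichotomize_mean_plus_sd()`);
* Cox proportional-hazards fits with per-SD hazard ratios and LRχ²
  bookkeeping, nested ΔLRχ² comparisons, Kaplan–Meier/log-rank suites,
  ln(time) proportionality checks and a subtype-heterogeneity interaction
  test (`fit_cox()`, `compare_nested()`, `km_logrank()`, `ph_check()`,
  `heterogeneity_test()`);
* a reproducible **synthetic cohort generator** (scaled-beta markers hitting
  the published median/SD targets, published clinical margins, Weibull PH
  survival calibrated to a 316/2498 event fraction) so everything is
  testable without patient data (`generate_cohort()`);
* an end-to-end pipeline and CLI (`run_full_analysis()`,
  `sensitivity_reclassification()`, `ihc4_cli()`).

The central statistic is the likelihood-ratio chi-square
`LRχ² = 2(ℓ_model − ℓ_null)`: a continuous score carries more prognostic
information than its categorisation when its model attains the larger LRχ².

## Worked example

```r
library(ihc4score)
cfg <- analysis_config(preset = "overall", n_patients = 1200, seed = 7,
                       stratify_by_study = FALSE)
rep <- run_full_analysis(cfg)
rep
```

```
Prognostic-score analysis report
  patients in: 1200 | chemo excluded: 77 | incomplete: 0 | analyzed: 1123
  events (10y): 133 | unclassified luminal: 191
  Univariable (combined):
    subtype B-like vs A-like     HR 0.95 (0.64-1.39)  LRchi2 0.1
    IHC4-score / 1 SD            HR 1.54 (1.30-1.82)  LRchi2 24.9
    C-score / 1 SD               HR 1.08 (0.92-1.28)  LRchi2 0.9
    PREDICT-score / 1 SD         HR 1.11 (0.94-1.32)  LRchi2 1.5
  P-heterogeneity (IHC4 x subtype): 0.72
```

Reading this: 77 chemotherapy recipients were excluded before modelling, and
follow-up was truncated at 10 years, leaving 1123 patients with 133
breast-cancer deaths.  The synthetic cohort's hazard is driven by the latent
IHC4 signal (per-SD HR 1.32 by default), so the continuous IHC4 model
recovers a strong effect (HR 1.54 per SD here, LRχ² 24.9) while the
dichotomised subtype contrast — a coarse function of the same markers —
retains almost none of it (LRχ² 0.1): the information-loss phenomenon the
package is built to quantify.  The C- and PREDICT-scores are near-null
because synthetic clinical factors are independent of the marker-driven
hazard.  The heterogeneity p-value (0.72) shows the IHC4 effect does not
differ between A-like and B-like disease.  `rep$table2`, `rep$table3`,
`rep$delta_lr` and `rep$km` hold the full matrices; with
`output_dir = ...` the report is written as CSV/JSON and regenerates
byte-identically from the same (config, seed).

Command-line equivalents:

```sh
Rscript -e 'ihc4score::ihc4_cli()' simulate --preset overall --n 2498 --seed 1 --out cohort.csv
Rscript -e 'ihc4score::ihc4_cli()' score --in cohort.csv --out scored.csv
Rscript -e 'ihc4score::ihc4_cli()' analyze --config config.json --out report_dir
```

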