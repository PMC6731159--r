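---
title: "Quantitative prognostic scores versus categorical subtypes in luminal breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative prognostic scores versus categorical subtypes in luminal breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihc4score)
```

## The scientific question

Hormone-receptor-positive ("luminal") breast cancer is conventionally split
into surrogate subtypes — luminal A-like and B-like — by dichotomising four
routine immunohistochemical markers (ER, PR, HER2, KI67).  Treatment
guidelines lean on these categories, but dichotomisation discards the
markers' dynamic range.  This package implements the alternative: combine the
*quantitative* marker measurements into the continuous IHC4 score, and ask —
with Cox proportional-hazards models of 10-year breast cancer-specific
survival — whether the continuous score carries more prognostic information
than the categorical subtype, measured by the likelihood-ratio chi-square
(LR$\chi^2$) of nested model comparisons.

## The scores

**IHC4.**  With $ER_{10} = ER\%/10$, $PR_{10} = PR\%/10$, HER2 coded per
`score_options()$her2_coding` and KI67 per `score_options()$ki67_unit`:

$$\mathrm{IHC4} = 94.7\,\{-0.100\,ER_{10} - 0.079\,PR_{10}
  + 0.586\,\mathrm{HER2} + 0.240\,\ln(1 + 10\,\mathrm{KI67})\}$$

Two conventions are deliberately configurable because the published text does
not pin them down:

* *KI67 unit.* The default feeds the 0–100 image-analysis percentage into
  the log term.  Back-calculation supports this: with percent-scale KI67 the
  score's attainable range comfortably covers the published summary
  statistics of the image-analysis score (mean 33, SD 65, maximum 289),
  whereas a fraction-scale KI67 caps the proliferation term far too low.
  `ki67_unit = "fraction"` restores the original visual-score convention.
* *HER2 coding.* The default uses the patient-level average of the ordinal
  Herceptest score (0–3): the image-analysis workflow scores all four
  markers, and the binary alternative cannot reach the published maximum.
  `her2_coding = "clinical_binary"` uses the 0/1 record status instead.

The published score minimum (−148) sits above the theoretical minimum of the
percent-convention formula (−169.5, at ER = PR = 100%, HER2 = KI67 = 0);
that is expected — the empirical minimum is attained by the most extreme
patient actually observed, not by the formula's corner.

**C-score** (clinical treatment score): indicator-coded nodal category
(0 / 1–3 / 4+), tumour-size category (≤1 / >1–2 / >2–3 / >3 cm), grade,
and age ≥ 65, scaled by 100.  Two printed details are handled explicitly:
the 0.930 multiplier is applied only to the $0.497\,T_{1-2}$ term exactly
as the equation is printed (`c_score_bracket_convention = "as_printed"`;
the whole-bracket alternative is available because the original grouping is
ambiguous), and the aromatase-inhibitor term is fixed at 0 since per-patient
endocrine regimen is not modelled.  The age indicator uses a closed boundary
(exactly 65 counts as ≥ 65); the text does not resolve this and the choice
affects a measure-zero set of ages.

**PREDICT (ER+)**: the v1 linear predictor over age, size (mm), nodes and
grade, natural logs, with the screen-detection term omitted (set to 0)
because detection mode is not modelled.  Grade enters linearly, so grade 3
minus grade 2 is exactly 0.7467 — a useful analytic spot check.

## Subtype rules

A-like requires homogeneous receptor expression (ER+ *and* PR+), HER2−, and
image-analysis KI67 ≤ 12% (the image-analysis cut-off corresponding to a
visual score of about 25%).  B-like requires ER+ and/or PR+ together with
KI67 > 12% or HER2+.  The rules are disjoint but not exhaustive: a
single-receptor-positive, HER2−, low-proliferating tumour matches neither.
Such patients are labelled `UNCLASSIFIED`, kept in all continuous-score
analyses, and excluded from subtype-specific models — the only reading that
keeps the two subtype counts and the overall cohort size arithmetically
consistent.  ER/PR positivity defaults to the historical record convention
(Allred > 2, i.e. strictly > 10% positive cells, taken from the clinical
record when available); the modern ≥ 1% rule is the sensitivity convention
and is always re-derived from the image percentages, because record statuses
encode the 10% rule and would otherwise make reclassification a no-op.
HER2 positivity uses the record status when present, else an averaged
Herceptest of 3 (all cores 3+).

## Analysis conventions

* Chemotherapy recipients are excluded from survival analyses (the ~7%
  prevalence is too low to stratify on), then complete-case filtering on the
  model covariates; exclusion counts are logged and conserved.
* Follow-up is administratively truncated at 10 years; later events become
  censorings at 10.
* Continuous scores are standardised by the pooled analysis-cohort sample SD
  (n−1), so hazard ratios are per 1 SD and comparable across scores.  The
  pooled SD is also used in study-stratified fits (per-stratum SDs are
  available via `fit_cox(per_sd = ...)` on the subset).
* Ties use the Efron approximation (times are continuous here, so this is
  inert, but it is configurable to Breslow).
* Quartiles use type-7 empirical quantile breaks with right-closed
  intervals: a value exactly on a break goes to the lower bin.
* The high/low IHC4 split is at mean + 1 SD of the pooled analysis cohort.
* Model information is compared by LR$\chi^2$ against the intercept-only
  null; nested contributions by $\Delta$LR$\chi^2 = 2\,\Delta\ell$ on the
  same rows.
* Proportionality is checked with covariate × ln(time) time-varying terms
  (the time transform is a package choice; the source analysis does not name
  one).
* Heterogeneity of the IHC4 effect across subtypes is a 1-df LR test of the
  score × subtype interaction, added to a model with score, subtype and
  adjustment terms.
* No multiplicity adjustment anywhere, matching the unadjusted reporting
  convention of this literature.

## The synthetic cohort: a stated world

No patient-level data are deposited, so the generator emulates the published
cohort and is itself first-class, tested code:

* **Markers.** ER, PR and KI67 are scaled-beta distributions whose shapes
  are solved at configuration time to hit the published median (SD) targets
  of 62% (34), 57% (38) and 9% (11); the beta family is a modelling choice —
  the true distribution family is not identifiable from summary statistics.
  HER2 is 3+ with probability 0.09; the 0/1+/2+ split among negatives
  (50/30/20) is unconstrained by any published number and fixed as a
  documented constant.  Rows with neither receptor positive are redrawn
  (luminal inclusion criterion), which nudges the realised ER/PR medians a
  few points above their marginal targets — within the stated ±10%
  tolerance.
* **Clinical factors.** Categorical margins follow the published
  overall/per-study tables (age 1.6/32.2/53.7/12.4%, grade 26/56/18%,
  size 65/32/2%, node-negative 61%, endocrine therapy 80%, chemotherapy 7%);
  continuous values are uniform within the drawn bracket.  The 1–3 vs 4+
  split of node-positive disease (72/28) is not published and is a fixed
  package constant.
* **Survival.** Weibull proportional hazards with shape 1.2 (mildly
  increasing hazard, plausible for a 10-year breast-cancer horizon), per-SD
  log hazard ratio defaulting to ln(1.32) (the published univariable IHC4
  effect), and the IHC4 score as the default latent driver.  The scale is
  calibrated analytically so the expected event fraction matches 316/2498.
  Censoring is uniform on [4, 10] years (entry-window width 6), which
  reproduces a ~7-year median follow-up; the real censoring distribution is
  unpublished and this stand-in is documented as synthetic.  Non-breast-
  cancer deaths are folded into censoring — a cause-specific analysis, not a
  competing-risks model.

What the generator does **not** emulate: between-study differences in the
IHC4 distribution beyond the margin presets, stage/morphology structure,
correlation between markers and clinical factors (they are independent by
construction), core-level image noise, and any real-world PH violation.  A
green test therefore establishes that the machinery is correct under the
stated world, not that the published hazard ratios are reproduced — those
depend on undeposited data and are out of reach by design.

## Determinism and numerics

A single run seed is fanned out to per-stage child seeds through a fixed
affine map modulo $2^{31}-1$ (`child_seed()`), so markers, clinical factors
and survival draws are independently reproducible.  Reports are pure
functions of (config, seed) and regenerate byte-identically.  The beta-shape
solver and the Weibull-scale calibration are deterministic numerical steps
(Nelder–Mead to residual < 1e−6; `uniroot` to 1e−10).  Degenerate inputs
fail loudly: zero-variance standardisation, fewer than four distinct values
for quartiles, empty groups in log-rank, covariates without variation,
non-luminal rows in subtype classification.  Inestimable report cells (e.g.
a tiny stratum with monotone likelihood) are rendered as flagged blanks
rather than aborting a whole run.

## Scaling of simulation-based tests

The acceptance suite runs at its stated scales (1000 null simulations at
n = 500; 500 recovery replicates at n = 2000 plus 200 at n = 5000; 200
information-loss replicates at n = 2000).  Secondary power/size illustrations
in the unit suite (log-rank power, PH-check power, heterogeneity size,
noise-covariate $\chi^2(1)$ behaviour) run at reduced replicate counts with
correspondingly generous Monte-Carlo tolerances, to keep the default test run
fast; they are checks of behaviour, not of the acceptance criteria.

## Worked example

```{r example}
cfg <- analysis_config(preset = "overall", n_patients = 1200, seed = 7,
                       stratify_by_study = FALSE)
rep <- suppressWarnings(run_full_analysis(cfg))
rep
rep$delta_lr
```

## Known limitations

* The package compares prognostic information; it does not estimate absolute
  chemotherapy benefit, model competing risks, or implement the Allred
  visual-scoring pipeline.
* Marker and clinical covariates are generated independently, so synthetic
  multivariable adjustment patterns (e.g. how much the PREDICT score
  attenuates the IHC4 effect) will not mirror a real cohort's.
* The C-score / PREDICT-score coefficient sets are fixed published
  constants; refitting them is out of scope.
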