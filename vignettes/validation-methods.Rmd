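---
title: "Validating prognostic mortality scores in older people living with HIV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating prognostic mortality scores in older people living with HIV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivprognosis)
```

## Scope and model

`hivprognosis` externally validates points-based prognostic mortality scores
for people living with HIV aged 70 years or older, against observed 5-year
all-cause mortality. The pipeline has five stages: cohort ingestion and
eligibility screening; windowed baseline-value resolution; clinical
transforms; score evaluation from auditable definition assets; and the
validation statistics (discrimination and calibration). Every stage is an
exported function; `score_validation()` runs them all and returns a classed
object.

The survival model underlying validation is the standard right-censored
setting: each subject contributes a follow-up time $t_i$ (years from entry,
truncated at the 5-year horizon and the administrative study end) and a
death indicator $d_i$. Deaths after the truncation point are recoded as
censored at truncation, because the score predicts mortality *within* the
horizon. Losses to follow-up are censored at the last known-alive date; no
death-registry lookup is modelled.

## Eligibility and baseline windows

A subject enters the validation cohort when aged $\ge 70$ at entry, HIV-1
infected, and with at least one CD4 count within 12 months of the entry
date. Baseline covariates are resolved per analyte as the measurement
closest to entry inside a $\pm$12-month window. Fixed conventions (chosen
once, for reproducibility):

* a "month" is 30.4375 days and a "year" 365.25 days, so the 12-month
  window is exactly 365.25 days on each side;
* when a before-entry and an after-entry measurement are exactly
  equidistant, the after-entry value wins — post-entry measurements better
  reflect the state at entry. When the two rules (nearest vs. after-entry
  preference) conflict beyond exact ties, *nearest wins*; the preference
  acts only as a tie-break;
* two same-day measurements of one analyte resolve to the last one listed,
  with a warning;
* age is exact fractional years at entry;
* BMI is exempt from the window by default (`bmi_mode = "unrestricted"`:
  the globally closest weight is used, with no time limit, even after
  exit), because stable patients rarely have their weight re-measured and a
  windowed rule would preferentially exclude them. `bmi_mode = "windowed"`
  applies the standard rule for sensitivity analyses.

HBsAg and HCV-antibody status arrive as resolved flags in the participant
table; the package does not re-resolve them from dated serology.

## Clinical transforms

* **eGFR** — CKD-EPI 2009 with the published piecewise constants (creatinine
  converted $\mu$mol/L $\to$ mg/dL by /88.4). The race coefficient is
  omitted by default because French cohorts do not record race; a flag
  restores it. Banding for scores is $[0,30)$, $[30,60)$, $[60,\infty)$,
  compared on exact (untruncated) values.
* **BMI** — weight/height$^2$; low BMI is $<18.5$ kg/m$^2$.
* **FIB-4** — age$\times$AST/(platelets$\times\sqrt{\text{ALT}}$); AST/ALT
  accepted in U/L $\equiv$ IU/L.
* **Flags and bands** — anaemia: haemoglobin $<13$ g/dL (men) / $<12$ g/dL
  (women); viral suppression: RNA $\le 50$ copies/mL; CD4 bands half-open on
  the left, $[0,200)$, $[200,350)$, $[350,500)$, $[500,\infty)$ — published
  band labels overlap at the boundaries, so the half-open-left convention is
  fixed here and used consistently.

## Score definition assets

Point tables and coefficients live in schema-validated JSON files under
`inst/extdata/`, not in code, so transcription is auditable (the tests
assert the Dat'AIDS range 0–73 and the age-band point structure directly on
the asset). Two assets are **synthetic stand-ins**, marked as such in their
filenames and `provenance` fields:

* `dataids_points_synthetic.json` — the original per-category point
  allocation is only published in non-redistributable supplementary
  material. The stand-in is constrained by every public fact: the component
  list, range 0–73, age 65–74 = 1 point and $\ge$75 = 8 points, the risk
  cut-points 0–3/4–13/14–19/$\ge$20 and the group-level predicted 5-year
  survival 0.95/0.90/0.80/0.53. Remaining per-category points are plausible
  values fixed once.
* `vacs2_coefficients_synthetic.json` — the published VACS 2.0 nomogram uses
  restricted cubic splines; the stand-in keeps the input list and risk
  directions with clamped linear terms, scaled once so the synthetic
  cohort's score distribution sits near the published median/IQR.

`vacs1_points.json` is a transcription of the published VACS 1.0 categorical
table (range 0–164). Conclusions about the *original* indices' numerical
performance should not be drawn from the stand-ins; the pipeline logic
(computability, imputation, comparison on common complete cases) is what
they exercise.

VACS 2.0 continuous inputs are range-clamped to each component's stated
domain before evaluation, so out-of-range labs saturate rather than
extrapolate. Albumin arrives in g/L and is converted to g/dL (/10) before
scoring and before the imputation comparison. The normal-value imputation
policy sets missing albumin to 4 g/dL, ALT to 25 IU/L and AST to 20 IU/L,
touches nothing else, records provenance flags, and is idempotent.

## Predicted survival and the constant-hazard bridge

The derivation study's baseline survival function is not republished, so the
default prediction mode is the group-level mapping with a constant-hazard
bridge for intermediate times: $S_g(t) = S_g(5)^{t/5}$, exact at $t=5$ and
reproducible from the published group-level predictions alone. Equivalently the predicted
cumulative hazard decomposes as $\hat H_i(t) = e^{\mathrm{PI}_i}\,\Lambda_0(t)$
with $\Lambda_0(t) = t/5$ and prognostic index
$\mathrm{PI}_i = \log(-\log S_{g(i)}(5))$. When a definition carries a
`baseline_survival` slot ($S_0(5)$ and coefficient $\lambda$), the
continuous form $S(t) = S_0(5)^{\exp(\lambda\,\text{score})\,t/5}$ is used
instead.

## Validation statistics

* **Harrell's C** — implemented in-package with the orientation and tie
  rules pinned down: a pair is comparable when the shorter time has the
  event (equal times: only death-vs-censored pairs, the death counted
  earlier); concordant when the earlier failure has the higher marker;
  marker ties count 1/2. The published source does not state a CI method,
  so a leave-one-subject-out jackknife SE with a normal interval is used —
  computed exactly in $O(n^2)$ from per-subject pair contributions — and is
  swappable. The test suite checks the statistic against a brute-force pair
  enumeration oracle and against `survival::concordance`.
* **Subgroups** — sex; CD4 $</\ge$ 350; CD4 nadir $</\ge$ 200; CD4 below/at
  or above the cohort median; RNA $</\ge$ 200 copies/mL. Degenerate
  subgroups are skipped with a warning.
* **Cox hazard ratios** — risk-group indicators with the low-risk group as
  reference (the published supplementary table reports pairwise HRs, which
  indicator coding reproduces; ordinal coding would not). Tie handling is
  unstated in the source; the Efron correction is the default, Breslow by
  flag. Fitting is delegated to `survival::coxph`; a group with no events is
  flagged unstable rather than silently reported.
* **Calibration** — the Poisson representation of a Cox model, single record
  per subject at the truncated exit time (follow-up is truncated at the
  5-year horizon before fitting, matching the prediction horizon; the
  split-follow-up variant of the representation is a noted alternative).
  Intercept: Poisson likelihood for $d_i$ with offset $\log \hat H_i$,
  whose MLE is $\hat\alpha = \log(\sum d_i / \sum \hat H_i)$. Slope: Poisson
  regression of $d_i$ on $\mathrm{PI}_i$ with offset $\log \Lambda_0(t_i)$.
  Subjects with same-day exit ($t_i = 0$) are shifted to 0.5 days to keep
  the offsets finite, with a message.
* **Score comparison** — each head-to-head comparison restricts to subjects
  for whom both scores are computable, then computes both C statistics on
  that common subset.

Reported percentages round half-up to one decimal, matching the reporting
style of cohort tables.

## The synthetic cohort

The generator emulates the study conditions: $n = 1330$ by default, entry
between 2014-06-01 and 2017-12-31, administrative censoring at
min(5 years, 2019-12-31). Because the cohort is mostly *prevalent* (patients
already in care when the window opens), 75% of entries fall in the first six
months of the window; this reproduces a mean follow-up near 4.2 years per
subject, as a purely incident design cannot. Covariates are drawn
independently from the published marginals — sex 75.8% male; age bands
60.8/36.5/2.6% over 70–74/75–84/$\ge$85; CD4 log-normal with median 553;
comorbidity prevalences 11.2% cancer, 13.3% CVD, 3.0% cirrhosis, 4.7% HCV,
1.3% HBV; continuous labs log-normal/normal matched to the published
median/IQR, with haemoglobin and BMI distributions calibrated so the derived
anaemia ($\approx$21.5%), low-BMI ($\approx$5.4%) and eGFR-band
($\approx$3.5/30/66.5%) prevalences land on their targets. AIDS history
(25%) is not published for this cohort and is an assumption. Missingness is
MCAR: albumin present in 34.1%, weight within the window in 68.3%, other
labs $\approx$99.5%, and is independent of event status by construction.

Survival times are exponential with hazard
$h_0 \exp(\lambda_{\mathrm{true}}\cdot\text{score})$. The defaults
$\lambda_{\mathrm{true}} = 0.105$ per point and $h_0 = 0.0092$/year were
solved once from $S(5) = \exp(-5\,h_0 e^{\lambda s})$ at the group median
scores 1/8/16/25 against the published group predictions
0.95/0.90/0.80/0.53, so group-level calibration checks are meaningful.
Loss to follow-up censors a configurable 11% of subjects uniformly over
(0, 5]. `hazard_model = "group_bridge"` instead simulates events exactly
from the packaged group-level predictions, which is the self-consistency
condition under which the calibration statistics should recover intercept 0
and slope 1 and is used by the parameter-recovery tests.

What the generator does **not** emulate: joint covariate dependence (e.g.
CD4 $\times$ anaemia — only marginals are published, so independence is the
default and a correlation hook is the natural extension), informative
censoring, COVID-era mortality, and the real score distribution's shape
(independent marginals give a slightly higher median total than observed).
Passing tests therefore demonstrate the pipeline's correctness and
statistical self-consistency, not the clinical performance of any score on
real data.

## Problem sizes and numerical choices

The test suite runs the generator at $n$ between 120 and 3000 and the
parameter-recovery checks at $n = 5000$ with fixed seeds; the brute-force
concordance oracle covers 100 random fixtures with $n \le 50$; the Cox
grid-search oracle uses a 0.001-step grid on an untied 8-subject fixture
(Efron = Breslow = the plain partial likelihood in the untied case). These
sizes keep each check well-powered (binomial/Greenwood tolerances of 3–4
standard errors) while the whole suite completes in about a minute.

Degenerate inputs: empty survival datasets, zero person-time, datasets
without events or comparable pairs, non-positive predicted hazards and
non-positive FIB-4/creatinine/height inputs all raise errors; unknown
analytes, malformed dates, wrong units and non-positive measurement values
are rejected row-by-row with line numbers at load time.

## Known limitations

* The two synthetic stand-in assets preclude numeric claims about the
  original Dat'AIDS and VACS 2.0 indices (the pipeline itself is agnostic:
  drop in a faithful asset file and everything downstream applies).
* Calibration of the VACS indices is not assessed — their survival
  equations are unpublished — mirroring the validation study's own scope.
* The Poisson calibration uses the single-record-per-subject variant;
  split-follow-up variants would relax the constant-baseline assumption
  within the horizon.
* Scores are computed once at baseline, never time-updated.
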