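# hivprognosis

External validation of prognostic mortality scores in older people living
with HIV.

## The problem

People living with HIV now routinely reach old age, and in this population
most deaths are driven by comorbidities rather than by HIV itself. Clinicians
need a simple way to stratify 5-year all-cause mortality risk when planning
preventive care. The Dat'AIDS score is a points-based index built from nine
routinely collected predictors — age band, CD4 cell count band, history of
non-HIV cancer, cardiovascular disease, eGFR band, cirrhosis, low BMI
(< 18.5 kg/m²), anaemia (haemoglobin < 13 g/dL in men, < 12 g/dL in women)
and HCV co-infection — with a theoretical range of 0–73 points and four risk
groups:

| risk group | score | predicted 5-year survival |
|------------|-------|---------------------------|
| low        | 0–3   | 0.95 |
| moderate   | 4–13  | 0.90 |
| high       | 14–19 | 0.80 |
| very high  | ≥ 20  | 0.53 |

This package implements the full external-validation pipeline for such a
score against observed survival in a cohort of people living with HIV aged
70 years or older, alongside the two comparator indices used in this field,
the VACS index 1.0 (categorical points over age, CD4, HIV-RNA, haemoglobin,
FIB-4, eGFR and HCV) and VACS 2.0 (a continuous score that adds albumin,
BMI, white cells and platelets).

The statistical core:

- **Discrimination** — Harrell's concordance statistic
  C = P(marker_i > marker_j | subject i fails first), computed over
  comparable pairs under right-censoring, with a leave-one-out jackknife
  confidence interval, overall and in pre-specified subgroups; hazard ratios
  across risk groups from a Cox proportional-hazards model (Efron ties).
- **Calibration** — the Poisson-regression representation of a Cox model:
  with predicted cumulative hazard Ĥᵢ = exp(PIᵢ)·Λ₀(tᵢ), the calibration
  intercept is the intercept of a Poisson model for the death indicator with
  offset log Ĥᵢ (closed form log(Σdᵢ/ΣĤᵢ)), and the calibration slope is the
  coefficient on the prognostic index PIᵢ with offset log Λ₀(tᵢ). Predicted
  versus observed Kaplan–Meier survival is also reported per risk group.
- **Cohort plumbing** — eligibility screening (age ≥ 70, HIV-1, a CD4 count
  within ±12 months of entry), baseline values selected as the measurement
  closest to entry within a ±12-month window (after-entry values win exact
  ties; BMI is exempt from the window by default), CKD-EPI eGFR, FIB-4,
  follow-up truncated at 5 years / study end, and completeness accounting
  with the normal-value imputation policy for albumin (4 g/dL), ALT
  (25 IU/L) and AST (20 IU/L).

Because the real cohort data are access-restricted, the package ships a
synthetic cohort generator that reproduces the published marginal structure
(sex, age bands, CD4, comorbidity prevalences, lab distributions, ~34%
albumin completeness, ~68% within-window BMI completeness, 11% loss to
follow-up) with exponential survival under a proportional-hazards model on
the true score. **Note:** the per-category Dat'AIDS point allocation and the
VACS 2.0 coefficients are synthetic stand-ins constrained by the published
facts (see the asset files' `provenance` fields and the vignette); do not
use them for clinical scoring.

## Worked example

```r
library(hivprognosis)

cohort_dir <- tempfile()
generate_cohort(synthetic_config(n = 1330, seed = 1), dir = cohort_dir)
val <- score_validation(file.path(cohort_dir, "participants.csv"),
                        file.path(cohort_dir, "measurements.csv"))
print(val)
```

```
External validation: 1330 screened, 1330 (100.0%) included
Deaths: 221 over 5284 person-years (4.18 per 100 PY)
Harrell's C = 0.713 (95% CI 0.678-0.748), 1312 subjects, 219 events
calibration intercept 0.138 (95% CI 0.005-0.270)
calibration slope     0.873 (95% CI 0.711-1.035)

Predicted vs observed 5-year survival by risk group:
      group   n deaths predicted observed difference
1       low 153      7      0.95     0.95       0.00
2  moderate 698     71      0.90     0.88       0.02
3      high 292     73      0.80     0.72       0.08
4 very_high 169     68      0.53     0.56      -0.03
```

Reading the output: 221 deaths over 5284 person-years give a mortality rate
of 4.18/100 PY; C = 0.71 means that in 71% of comparable pairs the subject
with the higher score died first (0.7–0.8 is conventionally "good"
discrimination); the calibration slope below 1 indicates the score's
predictions are somewhat too spread out in this simulated draw; and the
risk-group table compares each group's predicted 5-year survival with its
Kaplan–Meier estimate. `summary(val)` adds subgroup C statistics, hazard
ratios across risk groups, head-to-head comparisons with the VACS indices on
common complete cases, and the completeness table; `plot(val)` draws the
predicted-versus-observed panel. A command-line wrapper with `simulate`,
`score`, `validate` and `compare` subcommands is installed at
`inst/cli/hivprognosis.R`.

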