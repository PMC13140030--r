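{
  "name": "vacs2",
  "label": "VACS index 2.0 continuous score (synthetic stand-in coefficients)",
  "type": "continuous",
  "provenance": "SYNTHETIC STAND-IN. The published VACS index 2.0 is a continuous nomogram with restricted-cubic-spline terms whose coefficient tables are not redistributable here. This asset keeps the published input list (age, CD4, log10 HIV-1 RNA, haemoglobin, FIB-4, eGFR, HCV, albumin, white blood cells, platelets, BMI) and risk directions, replacing the spline terms with clamped linear contributions scaled once so that the synthetic validation cohort's score distribution lies near the published cohort median/IQR. Each contribution is slope*(clamped(x)-ref) with ref at the clamp end of lowest risk, so every contribution is non-negative. Do not use for clinical scoring.",
  "components": [
    {"covariate": "age",         "unit": "years",       "slope": 1.5,    "ref": 55,   "clamp": [55, 90]},
    {"covariate": "cd4",         "unit": "cells/mm3",   "slope": -0.015, "ref": 1000, "clamp": [0, 1000]},
    {"covariate": "log10_rna",   "unit": "log10 cp/mL", "slope": 4.0,    "ref": 1.3,  "clamp": [1.3, 7]},
    {"covariate": "hemoglobin",  "unit": "g/dL",        "slope": -4.0,   "ref": 16,   "clamp": [8, 16]},
    {"covariate": "fib4",        "unit": "unitless",    "slope": 3.0,    "ref": 0,    "clamp": [0, 7.5]},
    {"covariate": "egfr",        "unit": "mL/min/1.73m2","slope": -0.2,  "ref": 100,  "clamp": [0, 100]},
    {"covariate": "hcv",         "unit": "boolean",     "slope": 5.0,    "ref": 0,    "clamp": [0, 1]},
    {"covariate": "albumin_gdl", "unit": "g/dL",        "slope": -8.0,   "ref": 5,    "clamp": [2, 5]},
    {"covariate": "wbc",         "unit": "10^3/uL",     "slope": 1.5,    "ref": 4,    "clamp": [4, 12]},
    {"covariate": "platelets",   "unit": "10^3/uL",     "slope": -0.05,  "ref": 250,  "clamp": [50, 250]},
    {"covariate": "bmi",         "unit": "kg/m2",       "slope": -1.0,   "ref": 30,   "clamp": [15, 30]}
  ],
  "risk_groups": null,
  "baseline_survival": null
}
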