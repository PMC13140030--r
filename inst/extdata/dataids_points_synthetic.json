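{
  "name": "dataids",
  "label": "Dat'AIDS 5-year mortality score (synthetic stand-in point allocation)",
  "type": "categorical",
  "provenance": "SYNTHETIC STAND-IN. The original per-category point allocation of the Dat'AIDS score is published only in the derivation study's supplementary material, which is not redistributable here. This table is a reconstruction constrained by every publicly printed fact about the score: the predictor list (age, CD4 cell count, non-HIV cancer, cardiovascular disease, eGFR, cirrhosis, low BMI, anaemia, HCV co-infection), the theoretical range 0-73, the age component contributing 1 point for 65-74 years and 8 points for 75 years or older, and the published risk-group cut-points and group-level 5-year predicted survival. Per-category points for the remaining components are plausible values chosen once; do not use this file for clinical scoring.",
  "components": [
    {
      "covariate": "age",
      "unit": "years",
      "categories": [
        {"min": 0,   "max": 65,   "points": 0, "label": "<65"},
        {"min": 65,  "max": 75,   "points": 1, "label": "65-74"},
        {"min": 75,  "max": null, "points": 8, "label": ">=75"}
      ]
    },
    {
      "covariate": "cd4",
      "unit": "cells/mm3",
      "categories": [
        {"min": 0,   "max": 200,  "points": 12, "label": "<200"},
        {"min": 200, "max": 350,  "points": 6,  "label": "200-349"},
        {"min": 350, "max": 500,  "points": 3,  "label": "350-499"},
        {"min": 500, "max": null, "points": 0,  "label": ">=500"}
      ]
    },
    {
      "covariate": "non_hiv_cancer",
      "categories": [
        {"value": false, "points": 0,  "label": "no"},
        {"value": true,  "points": 10, "label": "yes"}
      ]
    },
    {
      "covariate": "cvd",
      "categories": [
        {"value": false, "points": 0, "label": "no"},
        {"value": true,  "points": 6, "label": "yes"}
      ]
    },
    {
      "covariate": "egfr",
      "unit": "mL/min/1.73m2",
      "categories": [
        {"min": 0,  "max": 30,   "points": 10, "label": "<30"},
        {"min": 30, "max": 60,   "points": 4,  "label": "30-59"},
        {"min": 60, "max": null, "points": 0,  "label": ">=60"}
      ]
    },
    {
      "covariate": "cirrhosis",
      "categories": [
        {"value": false, "points": 0,  "label": "no"},
        {"value": true,  "points": 12, "label": "yes"}
      ]
    },
    {
      "covariate": "low_bmi",
      "categories": [
        {"value": false, "points": 0, "label": "BMI >= 18.5"},
        {"value": true,  "points": 5, "label": "BMI < 18.5"}
      ]
    },
    {
      "covariate": "anemia",
      "categories": [
        {"value": false, "points": 0, "label": "no"},
        {"value": true,  "points": 6, "label": "yes"}
      ]
    },
    {
      "covariate": "hcv",
      "categories": [
        {"value": false, "points": 0, "label": "no"},
        {"value": true,  "points": 4, "label": "yes"}
      ]
    }
  ],
  "risk_groups": {
    "labels": ["low", "moderate", "high", "very_high"],
    "cutpoints": [4, 14, 20],
    "predicted_survival_5y": {
      "low": 0.95,
      "moderate": 0.90,
      "high": 0.80,
      "very_high": 0.53
    }
  },
  "baseline_survival": null
}
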