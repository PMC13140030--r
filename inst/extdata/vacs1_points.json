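{
  "name": "vacs1",
  "label": "VACS index 1.0 (categorical point system)",
  "type": "categorical",
  "provenance": "Transcribed from the published VACS index 1.0 definition (age, CD4 cell count, HIV-1 RNA, haemoglobin, FIB-4, eGFR, HCV co-infection; total range 0-164).",
  "components": [
    {
      "covariate": "age",
      "unit": "years",
      "categories": [
        {"min": 0,  "max": 50,   "points": 0,  "label": "<50"},
        {"min": 50, "max": 65,   "points": 12, "label": "50-64"},
        {"min": 65, "max": null, "points": 27, "label": ">=65"}
      ]
    },
    {
      "covariate": "cd4",
      "unit": "cells/mm3",
      "categories": [
        {"min": 0,   "max": 50,   "points": 29, "label": "<50"},
        {"min": 50,  "max": 100,  "points": 28, "label": "50-99"},
        {"min": 100, "max": 200,  "points": 10, "label": "100-199"},
        {"min": 200, "max": 350,  "points": 6,  "label": "200-349"},
        {"min": 350, "max": 500,  "points": 6,  "label": "350-499"},
        {"min": 500, "max": null, "points": 0,  "label": ">=500"}
      ]
    },
    {
      "covariate": "hiv_rna",
      "unit": "copies/mL",
      "categories": [
        {"min": 0,      "max": 500,    "points": 0,  "label": "<500"},
        {"min": 500,    "max": 100000, "points": 7,  "label": "500-99999"},
        {"min": 100000, "max": null,   "points": 14, "label": ">=100000"}
      ]
    },
    {
      "covariate": "hemoglobin",
      "unit": "g/dL",
      "categories": [
        {"min": 14, "max": null, "points": 0,  "label": ">=14"},
        {"min": 12, "max": 14,   "points": 10, "label": "12-13.9"},
        {"min": 10, "max": 12,   "points": 22, "label": "10-11.9"},
        {"min": 0,  "max": 10,   "points": 38, "label": "<10"}
      ]
    },
    {
      "covariate": "fib4",
      "unit": "unitless",
      "categories": [
        {"min": 0,    "max": 1.45, "points": 0,  "label": "<1.45"},
        {"min": 1.45, "max": 3.25, "points": 6,  "label": "1.45-3.25"},
        {"min": 3.25, "max": null, "points": 25, "label": ">3.25"}
      ]
    },
    {
      "covariate": "egfr",
      "unit": "mL/min/1.73m2",
      "categories": [
        {"min": 60, "max": null, "points": 0,  "label": ">=60"},
        {"min": 45, "max": 60,   "points": 6,  "label": "45-59.9"},
        {"min": 30, "max": 45,   "points": 8,  "label": "30-44.9"},
        {"min": 0,  "max": 30,   "points": 26, "label": "<30"}
      ]
    },
    {
      "covariate": "hcv",
      "categories": [
        {"value": false, "points": 0, "label": "no"},
        {"value": true,  "points": 5, "label": "yes"}
      ]
    }
  ],
  "risk_groups": null,
  "baseline_survival": null
}
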