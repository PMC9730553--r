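{
  "instrument": "FDD11",
  "schema_version": "1.0",
  "provenance": "Published calibration of the WHO Functioning and Disability Disaggregation tool (FDD11): final item thresholds with standard errors, extreme-score anchor abilities, 0-100 severity cut-offs and the sum-score conversion table from the pooled Model Disability Survey implementations (11 countries, 2014-2019). Thresholds are on the recoded response scale.",
  "items": [
    {
      "id": "Q01",
      "question": "difficulty seeing, even if wearing glasses",
      "max_category": 3,
      "location": -0.08,
      "infit": 1.43,
      "thresholds": [-0.4, -0.04, 0.2],
      "threshold_ses": [0.01, 0.02, 0.02]
    },
    {
      "id": "Q02",
      "question": "difficulty hearing, even if using a hearing aid",
      "max_category": 2,
      "location": 1.2,
      "infit": 0.92,
      "thresholds": [0.66, 1.74],
      "threshold_ses": [0.01, 0.03]
    },
    {
      "id": "Q03",
      "question": "difficulty walking or climbing steps",
      "max_category": 3,
      "location": 0.17,
      "infit": 0.81,
      "thresholds": [-0.11, 0.18, 0.45],
      "threshold_ses": [0.01, 0.02, 0.03]
    },
    {
      "id": "Q04",
      "question": "difficulty remembering or concentrating",
      "max_category": 3,
      "location": 0.38,
      "infit": 0.89,
      "thresholds": [-0.57, 0.7, 1.01],
      "threshold_ses": [0.01, 0.02, 0.03]
    },
    {
      "id": "Q05",
      "question": "difficulty with self-care such as washing all over or dressing",
      "max_category": 2,
      "location": 1.26,
      "infit": 0.71,
      "thresholds": [0.83, 1.69],
      "threshold_ses": [0.01, 0.03]
    },
    {
      "id": "Q06",
      "question": "difficulty sleeping because of your health",
      "max_category": 2,
      "location": 0.18,
      "infit": 0.83,
      "thresholds": [-0.44, 0.79],
      "threshold_ses": [0.01, 0.02]
    },
    {
      "id": "Q07",
      "question": "difficulty doing household tasks because of your health",
      "max_category": 2,
      "location": 0.31,
      "infit": 0.76,
      "thresholds": [-0.26, 0.87],
      "threshold_ses": [0.01, 0.02]
    },
    {
      "id": "Q08",
      "question": "difficulty joining community activities because of your health",
      "max_category": 2,
      "location": 0.15,
      "infit": 0.88,
      "thresholds": [-0.41, 0.71],
      "threshold_ses": [0.01, 0.02]
    },
    {
      "id": "Q09",
      "question": "feeling sad, low or depressed / worried, nervous or anxious (testlet)",
      "max_category": 4,
      "location": 0.18,
      "infit": 1.01,
      "thresholds": [-1.45, -0.04, 1.04, 1.19],
      "threshold_ses": [0.01, 0.01, 0.02, 0.04]
    },
    {
      "id": "Q10",
      "question": "difficulty getting along with people close to you",
      "max_category": 3,
      "location": 0.5,
      "infit": 0.99,
      "thresholds": [0.38, 0.43, 0.69],
      "threshold_ses": [0.01, 0.02, 0.03]
    },
    {
      "id": "Q11",
      "question": "bodily aches or pains",
      "max_category": 4,
      "location": -0.31,
      "infit": 0.96,
      "thresholds": [-1.48, -0.67, 0.33, 0.58],
      "threshold_ses": [0.01, 0.01, 0.02, 0.03]
    }
  ],
  "anchors": {
    "theta_min": -3.71,
    "theta_max": 4.18
  },
  "cutoffs": {
    "c1": 4.3,
    "c2": 22.6,
    "c3": 40.8
  },
  "score_table": [
    {
      "sum_score": 0,
      "theta": -3.71,
      "se": null,
      "score_0_100": 0,
      "level": "No"
    },
    {
      "sum_score": 1,
      "theta": -2.91,
      "se": 1.02,
      "score_0_100": 10.12,
      "level": "Mild"
    },
    {
      "sum_score": 2,
      "theta": -2.18,
      "se": 0.731,
      "score_0_100": 19.36,
      "level": "Mild"
    },
    {
      "sum_score": 3,
      "theta": -1.74,
      "se": 0.605,
      "score_0_100": 24.93,
      "level": "Moderate"
    },
    {
      "sum_score": 4,
      "theta": -1.42,
      "se": 0.531,
      "score_0_100": 28.99,
      "level": "Moderate"
    },
    {
      "sum_score": 5,
      "theta": -1.17,
      "se": 0.481,
      "score_0_100": 32.23,
      "level": "Moderate"
    },
    {
      "sum_score": 6,
      "theta": -0.952,
      "se": 0.445,
      "score_0_100": 34.94,
      "level": "Moderate"
    },
    {
      "sum_score": 7,
      "theta": -0.766,
      "se": 0.418,
      "score_0_100": 37.29,
      "level": "Moderate"
    },
    {
      "sum_score": 8,
      "theta": -0.601,
      "se": 0.397,
      "score_0_100": 39.39,
      "level": "Moderate"
    },
    {
      "sum_score": 9,
      "theta": -0.45,
      "se": 0.38,
      "score_0_100": 41.3,
      "level": "Severe"
    },
    {
      "sum_score": 10,
      "theta": -0.31,
      "se": 0.368,
      "score_0_100": 43.08,
      "level": "Severe"
    },
    {
      "sum_score": 11,
      "theta": -0.179,
      "se": 0.358,
      "score_0_100": 44.74,
      "level": "Severe"
    },
    {
      "sum_score": 12,
      "theta": -0.0536,
      "se": 0.351,
      "score_0_100": 46.33,
      "level": "Severe"
    },
    {
      "sum_score": 13,
      "theta": 0.0674,
      "se": 0.346,
      "score_0_100": 47.87,
      "level": "Severe"
    },
    {
      "sum_score": 14,
      "theta": 0.186,
      "se": 0.343,
      "score_0_100": 49.37,
      "level": "Severe"
    },
    {
      "sum_score": 15,
      "theta": 0.303,
      "se": 0.341,
      "score_0_100": 50.85,
      "level": "Severe"
    },
    {
      "sum_score": 16,
      "theta": 0.419,
      "se": 0.342,
      "score_0_100": 52.33,
      "level": "Severe"
    },
    {
      "sum_score": 17,
      "theta": 0.537,
      "se": 0.344,
      "score_0_100": 53.82,
      "level": "Severe"
    },
    {
      "sum_score": 18,
      "theta": 0.657,
      "se": 0.349,
      "score_0_100": 55.34,
      "level": "Severe"
    },
    {
      "sum_score": 19,
      "theta": 0.781,
      "se": 0.355,
      "score_0_100": 56.91,
      "level": "Severe"
    },
    {
      "sum_score": 20,
      "theta": 0.91,
      "se": 0.364,
      "score_0_100": 58.55,
      "level": "Severe"
    },
    {
      "sum_score": 21,
      "theta": 1.05,
      "se": 0.375,
      "score_0_100": 60.28,
      "level": "Severe"
    },
    {
      "sum_score": 22,
      "theta": 1.19,
      "se": 0.39,
      "score_0_100": 62.14,
      "level": "Severe"
    },
    {
      "sum_score": 23,
      "theta": 1.35,
      "se": 0.41,
      "score_0_100": 64.16,
      "level": "Severe"
    },
    {
      "sum_score": 24,
      "theta": 1.53,
      "se": 0.435,
      "score_0_100": 66.42,
      "level": "Severe"
    },
    {
      "sum_score": 25,
      "theta": 1.73,
      "se": 0.47,
      "score_0_100": 69.01,
      "level": "Severe"
    },
    {
      "sum_score": 26,
      "theta": 1.98,
      "se": 0.518,
      "score_0_100": 72.09,
      "level": "Severe"
    },
    {
      "sum_score": 27,
      "theta": 2.28,
      "se": 0.591,
      "score_0_100": 75.95,
      "level": "Severe"
    },
    {
      "sum_score": 28,
      "theta": 2.7,
      "se": 0.716,
      "score_0_100": 81.27,
      "level": "Severe"
    },
    {
      "sum_score": 29,
      "theta": 3.41,
      "se": 1,
      "score_0_100": 90.2,
      "level": "Severe"
    },
    {
      "sum_score": 30,
      "theta": 4.18,
      "se": null,
      "score_0_100": 100,
      "level": "Severe"
    }
  ]
}
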