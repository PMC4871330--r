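[
  {
    "label": "C",
    "n": 12,
    "mean": {
      "eating_time": 378.61,
      "ruminating_time": 583.23,
      "eating_chews": 29270,
      "ruminating_chews": 40760,
      "bolus": 614.5,
      "chews_per_minute": 75.74,
      "chews_per_bolus": 65.87,
      "lying_time": 679.65,
      "walking_time": 41.74,
      "lying_bouts": 9.79,
      "standing_bouts": 119.63,
      "walking_bouts": 111.17,
      "strides": 1075.17,
      "stride_duration": 1830,
      "stride_distance": 131
    },
    "sd": {
      "eating_time": 71.4,
      "ruminating_time": 56.28,
      "eating_chews": 7210,
      "ruminating_chews": 4190,
      "bolus": 60.74,
      "chews_per_minute": 4.7,
      "chews_per_bolus": 3.8,
      "lying_time": 74.13,
      "walking_time": 5.99,
      "lying_bouts": 1.6,
      "standing_bouts": 17.17,
      "walking_bouts": 16.28,
      "strides": 151.51,
      "stride_duration": 104,
      "stride_distance": 14
    },
    "nrs_values": [1, 1.5, 2],
    "nrs_probs": [0.17, 0.17, 0.66],
    "correlations": [
      [
        "standing_bouts",
        "walking_bouts",
        "0.98"
      ]
    ]
  },
  {
    "label": "LI",
    "n": 19,
    "mean": {
      "eating_time": 301.93,
      "ruminating_time": 537.37,
      "eating_chews": 22320,
      "ruminating_chews": 36900,
      "bolus": 533.96,
      "chews_per_minute": 73.97,
      "chews_per_bolus": 69.85,
      "lying_time": 784.38,
      "walking_time": 37.85,
      "lying_bouts": 9.54,
      "standing_bouts": 107.684,
      "walking_bouts": 99.411,
      "strides": 950.82,
      "stride_duration": 1970,
      "stride_distance": 106
    },
    "sd": {
      "eating_time": 57.16,
      "ruminating_time": 59.63,
      "eating_chews": 4780,
      "ruminating_chews": 5780,
      "bolus": 120.76,
      "chews_per_minute": 5.65,
      "chews_per_bolus": 13.91,
      "lying_time": 130.56,
      "walking_time": 7.06,
      "lying_bouts": 3.35,
      "standing_bouts": 15.1831975134261,
      "walking_bouts": 14.3791951214755,
      "strides": 176.15,
      "stride_duration": 150,
      "stride_distance": 16
    },
    "nrs_values": [2.5, 3],
    "nrs_probs": [0.5, 0.5],
    "correlations": [
      [
        "standing_bouts",
        "walking_bouts",
        "0.98"
      ]
    ]
  },
  {
    "label": "LII",
    "n": 11,
    "mean": {
      "eating_time": 301.93,
      "ruminating_time": 537.37,
      "eating_chews": 22320,
      "ruminating_chews": 36900,
      "bolus": 533.96,
      "chews_per_minute": 73.97,
      "chews_per_bolus": 69.85,
      "lying_time": 784.38,
      "walking_time": 37.85,
      "lying_bouts": 9.54,
      "standing_bouts": 92.48,
      "walking_bouts": 84.445,
      "strides": 950.82,
      "stride_duration": 1970,
      "stride_distance": 106
    },
    "sd": {
      "eating_time": 57.16,
      "ruminating_time": 59.63,
      "eating_chews": 4780,
      "ruminating_chews": 5780,
      "bolus": 120.76,
      "chews_per_minute": 5.65,
      "chews_per_bolus": 13.91,
      "lying_time": 130.56,
      "walking_time": 7.06,
      "lying_bouts": 3.35,
      "standing_bouts": 15.1831975134261,
      "walking_bouts": 14.3791951214755,
      "strides": 176.15,
      "stride_duration": 150,
      "stride_distance": 16
    },
    "nrs_values": 3.5,
    "nrs_probs": 1,
    "correlations": [
      [
        "standing_bouts",
        "walking_bouts",
        "0.98"
      ]
    ]
  },
  {
    "label": "LIII",
    "n": 11,
    "mean": {
      "eating_time": 301.93,
      "ruminating_time": 537.37,
      "eating_chews": 22320,
      "ruminating_chews": 36900,
      "bolus": 533.96,
      "chews_per_minute": 73.97,
      "chews_per_bolus": 69.85,
      "lying_time": 784.38,
      "walking_time": 37.85,
      "lying_bouts": 9.54,
      "standing_bouts": 87.05,
      "walking_bouts": 79.1,
      "strides": 950.82,
      "stride_duration": 1970,
      "stride_distance": 106
    },
    "sd": {
      "eating_time": 57.16,
      "ruminating_time": 59.63,
      "eating_chews": 4780,
      "ruminating_chews": 5780,
      "bolus": 120.76,
      "chews_per_minute": 5.65,
      "chews_per_bolus": 13.91,
      "lying_time": 130.56,
      "walking_time": 7.06,
      "lying_bouts": 3.35,
      "standing_bouts": 15.1831975134261,
      "walking_bouts": 14.3791951214755,
      "strides": 176.15,
      "stride_duration": 150,
      "stride_distance": 16
    },
    "nrs_values": [4, 4.5],
    "nrs_probs": [0.5, 0.5],
    "correlations": [
      [
        "standing_bouts",
        "walking_bouts",
        "0.98"
      ]
    ]
  }
]
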