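{
  "version": "1.0",
  "comment": "Uniform sampling intervals for random root-system generation. Units: mm, days, degrees. Intervals chosen once so that large generated libraries stay inside realistic fibrous/tap trait envelopes.",
  "fibrous": {
    "n_axes": [
      1,
      20
    ],
    "duration_days": [
      10,
      22
    ],
    "elong_coeff": [
      8,
      16
    ],
    "d_axis_mm": [
      0.2,
      0.4
    ],
    "d_min_mm": [
      0.06,
      0.12
    ],
    "diam_ratio": [
      0.25,
      0.5
    ],
    "diam_cv": [
      0.1,
      0.3
    ],
    "interbranch_mm": [
      2.5,
      6.0
    ],
    "insertion_angle_mean_deg": [
      40,
      70
    ],
    "insertion_angle_sd_deg": [
      5,
      15
    ],
    "tropism_strength": [
      0.03,
      0.12
    ],
    "direction_noise_sd_deg": [
      5,
      15
    ],
    "sec_growth_coeff": [
      0,
      0
    ]
  },
  "tap": {
    "n_axes": [
      1,
      1
    ],
    "duration_days": [
      10,
      22
    ],
    "elong_coeff": [
      8,
      16
    ],
    "d_axis_mm": [
      0.3,
      0.8
    ],
    "d_min_mm": [
      0.06,
      0.12
    ],
    "diam_ratio": [
      0.25,
      0.45
    ],
    "diam_cv": [
      0.1,
      0.3
    ],
    "interbranch_mm": [
      2.5,
      6.0
    ],
    "insertion_angle_mean_deg": [
      40,
      70
    ],
    "insertion_angle_sd_deg": [
      5,
      15
    ],
    "tropism_strength": [
      0.1,
      0.3
    ],
    "direction_noise_sd_deg": [
      5,
      15
    ],
    "sec_growth_coeff": [
      0.0002,
      0.002
    ]
  }
}
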