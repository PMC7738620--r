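{
  "R1_deltaRR": {
    "response": "delta_rr_mean",
    "units": "ms",
    "coefficients": {
      "(Intercept)": 1249.37,
      "vo2max": 12.32,
      "training_load": 0.36,
      "hr_max": -8.83,
      "rpe": -5.90,
      "perceived_fatigue": -28.41
    },
    "adj_r2": 0.322,
    "aic_published": 1805,
    "note": "Abstract/results text prints the RPE coefficient rounded to -5.8; the model table value -5.90 is canonical here."
  },
  "R1pp_deltaLnRMSSD": {
    "response": "delta_ln_rmssd",
    "units": "ln(ms)",
    "coefficients": {
      "(Intercept)": 1.647,
      "vo2max": 0.042,
      "training_load": 0.002,
      "hr_max": -0.017,
      "rpe": -0.019,
      "perceived_fatigue": -0.100,
      "stress": 0.092
    },
    "adj_r2": 0.141,
    "aic_published": 229.9
  },
  "coach_deltaRR": {
    "response": "delta_rr_mean",
    "units": "ms",
    "coefficients": {
      "(Intercept)": 689.62,
      "wb": -14.36,
      "hr_max": -2.06,
      "training_load": 0.35
    },
    "adj_r2": 0.194,
    "aic_published": 2033,
    "note": "Field-friendly variant: uses the summed well-being score and omits VO2max, which is rarely measured outside the laboratory."
  }
}
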