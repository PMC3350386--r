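{
  "generator": {
    "n_hospitals": 40,
    "hospital_size_law": {"mean": 600, "dispersion": 2},
    "sigma2_hospital": 0.3,
    "beta": {
      "intercept": -4.6052,
      "age": 0.0296,
      "sex": 0.1823,
      "paralysis": 1.3863,
      "fluid_electrolyte": 0.9163
    },
    "comorbidity_prevalences": {"paralysis": 0.03, "fluid_electrolyte": 0.1},
    "psi_name": "du",
    "seed": 7
  },
  "min_cases": 30,
  "bootstrap_reps": 200,
  "alpha": 0.05,
  "zero_policy": "truncate",
  "seed": 7,
  "out_dir": "psival-example-run"
}
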