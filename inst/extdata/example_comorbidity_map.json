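{
  "congestive_heart_failure": ["428"],
  "paralysis": ["342", "343", "344"],
  "other_neuro": ["330", "331", "332", "333", "334", "335", "340", "341"],
  "diabetes_chronic": ["2504", "2505", "2506", "2507"],
  "weight_loss": ["260", "261", "262", "263"],
  "fluid_electrolyte": ["276"]
}
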