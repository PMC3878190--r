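{
  "prevalence": 0.0004,
  "alpha": 0.05,
  "power": 0.95,
  "auc0": 0.6,
  "ratio": 1,
  "snps": [
    {
      "id": "snpA",
      "mode": "conditional",
      "freq_case": [0.25, 0.5, 0.25],
      "freq_control": [0.36, 0.48, 0.16]
    },
    {
      "id": "snpB",
      "mode": "population_rr",
      "freq_pop": [0.81, 0.18, 0.01],
      "rr": [1, 1.8, 3.24]
    },
    {
      "id": "snpC",
      "mode": "population_rr",
      "maf": 0.25,
      "rr": [1, 1.5, 2.25]
    }
  ]
}
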