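{
  "name": "nsclc-ici-18-gene-panel",
  "k": 2,
  "genes": ["ZFHX3", "NTRK3", "EPHA7", "EPHA5", "NF2", "ABL1", "MAX",
            "PARP1", "PAX5", "PGR", "FLT3", "MRE11A", "PIK3C3", "INHBA",
            "RET", "EPHA3", "MET", "NOTCH1"],
  "prevalence": {
    "ZFHX3": 0.08, "NTRK3": 0.06, "EPHA7": 0.05, "EPHA5": 0.08,
    "NF2": 0.03, "ABL1": 0.02, "MAX": 0.02, "PARP1": 0.01,
    "PAX5": 0.01, "PGR": 0.04, "FLT3": 0.03, "MRE11A": 0.02,
    "PIK3C3": 0.04, "INHBA": 0.03, "RET": 0.03, "EPHA3": 0.11,
    "MET": 0.04, "NOTCH1": 0.04
  }
}
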