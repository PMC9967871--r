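{
  "description": "Example mapping from cumulative CaCl2 added to the chamber (mM) to free [Ca2+] (uM) in the respiration buffer. Free-calcium speciation is not computed by this package; ladders are supplied by the user (e.g. from a chelator-equilibrium program). The first rung (0.3 mM -> 0.39 uM) is the assay's reported anchor; the remaining rungs are synthetic placeholders for demonstration only.",
  "synthetic_rungs": [0.55, 0.8, 1.05],
  "ladder": [
    {"cacl2_mM": 0.3,  "free_ca_uM": 0.39},
    {"cacl2_mM": 0.55, "free_ca_uM": 1.6},
    {"cacl2_mM": 0.8,  "free_ca_uM": 8.5},
    {"cacl2_mM": 1.05, "free_ca_uM": 52.0}
  ]
}
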