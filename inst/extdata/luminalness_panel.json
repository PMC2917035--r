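{
  "comment": "RPPA luminalness classifier panel: +1 = luminal-A-associated (ER function), -1 = luminal-B-associated (HER2 level/activity, apoptosis, protein synthesis, cell cycle). Bcl2 counted once (+1). collagenVI (stroma, direction unassigned) excluded by default; add it here with a sign to include it. Cutoff is an externally established constant: score >= cutoff -> lumA.",
  "weights": {
    "ER": 1,
    "PR": 1,
    "Bcl2": 1,
    "HER2": -1,
    "pHER2_Y1248": -1,
    "caspase7_cleaved": -1,
    "PARP_cleaved": -1,
    "pP70S6K": -1,
    "pS6": -1,
    "cyclinB1": -1
  },
  "cutoff": -0.907
}
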