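{
  "F": ["Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8"],
  "LT": ["FC5", "T7", "CP5"],
  "RT": ["FC6", "T8", "CP6"],
  "C": ["FC1", "FC2", "C3", "Cz", "C4", "CP1", "CP2"],
  "PO": ["P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "O1", "Oz", "O2"]
}
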