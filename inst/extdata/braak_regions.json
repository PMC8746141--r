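{
  "I": ["entorhinal"],
  "II": ["hippocampus"],
  "III": ["parahippocampal"],
  "IV": ["rostralanteriorcingulate", "caudalanteriorcingulate"],
  "V": ["cuneus", "pericalcarine", "lateraloccipital", "lingual"]
}
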