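{
  "n_clusters": 327,
  "n_multiread": 163,
  "n_multilibrary": 87,
  "n_shared_normal_tumor": 56,
  "n_intronic": 140,
  "n_novel": 316,
  "n_verified": 19,
  "n_attempted": 21
}
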