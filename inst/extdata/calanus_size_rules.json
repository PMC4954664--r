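{
  "note": "ASSUMED stage-specific prosome-length thresholds (mm) separating Calanus finmarchicus / C. glacialis / C. hyperboreus. Published studies derive such cut-points from the size distribution of each dataset; these defaults are plausible literature-scale values and should be replaced by dataset-specific cut-points whenever length data are available.",
  "species": ["finmarchicus", "glacialis", "hyperboreus"],
  "rules": [
    {"stage": "CIV", "cuts_mm": [1.70, 2.40]},
    {"stage": "CV", "cuts_mm": [2.45, 3.40]},
    {"stage": "CVI", "cuts_mm": [2.90, 3.90]}
  ]
}
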