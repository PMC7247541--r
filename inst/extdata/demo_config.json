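{
  "seed": 42,
  "outdir": "msap_demo_out",
  "simulate": {},
  "n_perm": {"amova": 499, "mantel": 499, "moran": 99, "locus": 199},
  "alpha": 0.05,
  "correction": "bonferroni",
  "nmds_restarts": 5
}
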