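{
  "seed": 1,
  "simulate": {
    "n_genes": 20,
    "n_chroms": 2,
    "tract_len_range": [6, 10],
    "library_size": 50000,
    "n_replicates": 2,
    "dispersion": 0,
    "treatment": "Ysh1AA",
    "control": "WT"
  },
  "flank": 500,
  "min_len": 5,
  "score_min": 3,
  "window": 1000,
  "exclusion": 50,
  "pseudocount": 3,
  "ratio_threshold": 2,
  "motif_n": 10,
  "k_range": [5, 10],
  "blacklist_top_n": 5,
  "metagene_upstream": 20,
  "metagene_downstream": 20,
  "terminator_min_len": 6
}
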