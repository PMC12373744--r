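{
  "out_dir": "cascnet_demo",
  "master_seed": 1,
  "simulate": {
    "n_td": 69,
    "n_et": 71,
    "n_hc": 80,
    "n_regions": 8,
    "vertices_per_region": 100,
    "use_table1_cascade": true
  },
  "group_diff": {
    "n_iter": 300
  },
  "cascn": {
    "n_perm": 300
  },
  "classify": {
    "n_repeats": 200,
    "n_resamples": 500,
    "n_trees": 200
  }
}
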