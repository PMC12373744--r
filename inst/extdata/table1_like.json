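{
  "out_dir": "cascnet_out",
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
    "cluster_forming_p": 0.01,
    "alpha": 0.05,
    "n_iter": 1000,
    "covariates": ["age", "sex"]
  },
  "scn": {
    "seeds_td": ["PCUN.R"],
    "seeds_et": ["MOF.R", "CUN.L"],
    "correction": "grf",
    "cluster_forming_p": 0.01,
    "alpha": 0.05
  },
  "cascn": {
    "order": 1,
    "min_cluster": 10,
    "n_perm": 1000,
    "z_threshold": 1,
    "alpha": 0.05
  },
  "classify": {
    "feature_set": "combined",
    "n_repeats": 1000,
    "cv_folds": 10,
    "threshold": 500,
    "mode": "count_threshold",
    "n_resamples": 1000,
    "ratio": 0.75,
    "n_trees": 500
  }
}
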