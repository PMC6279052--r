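# Bundled demonstration cohort: 200 tumors + 50 normals, 300 immune-panel
# genes, three planted evasion clusters of 40 patients each with distinct
# mechanism signatures, one marker gene per cluster, and histology labels
# biased toward ILC in cluster 1. Log2-scale values; noise SD 1.
simulate:
  n_genes: 300
  n_tumor: 200
  n_normal: 50
  layers:
    - {n_genes: 60, n_cols: 40, mu: 2}
    - {n_genes: 60, n_cols: 40, mu: 2}
    - {n_genes: 60, n_cols: 40, mu: 2}
  mechanism_plan:
    "1": ["M1", "M4"]
    "2": ["M2"]
    "3": ["M5"]
  label_plan:
    name: histology
    values: ["IDC", "ILC"]
    base_probs: [0.8, 0.2]
    odds:
      "1": {ILC: 8}
  marker_plan: {n_per_cluster: 1, delta: 3}
  noise_sd: 1
min_fraction: 0.05
seed: 101
de: {p_thresh: 0.05, fc_thresh: 1}
tree: {min_split: 20, min_leaf: 7, cp: 0.01, folds: 5}
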