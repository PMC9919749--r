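{
  "package": "predsip",
  "version": "0.1.0",
  "seed": 20240801,
  "config_hash": "15b767ec",
  "inputs": {
    "counts": "counts.tsv",
    "fractions": "fractions.tsv",
    "meta": "meta.tsv",
    "taxonomy": "taxonomy.tsv"
  },
  "settings": {
    "heavy": {
      "lo": 1.851,
      "hi": 1.872,
      "label": "heavy"
    },
    "light": {
      "lo": 1.805,
      "hi": 1.819,
      "label": "light"
    },
    "filter": {
      "genus_min_heavy_relab": 0.01,
      "asv_min_heavy_relab": 0.001,
      "ef_threshold": 0.1,
      "pseudocount": 0.5
    },
    "policy": "max_copies",
    "predator_threshold": 94.5,
    "alpha": 0.05,
    "bh_family": "per_variable"
  },
  "n_ef_records": 8,
  "n_labeled": 7,
  "missing_12C_groups": [],
  "outputs": {
    "ef": "ef.tsv"
  }
}
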