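{
  "required": {
    "parameters": "object",
    "de": "object",
    "scan": "object",
    "overlap": "object"
  },
  "sections": {
    "parameters": {
      "required": {
        "seed": "number",
        "n_genes": "number",
        "n_regulated": "number",
        "n_replicates": "number",
        "de_test": "string",
        "fold_cut": "number",
        "q_cut": "number",
        "direction": "string",
        "spacing_divisor": "number",
        "min_hits": "number",
        "min_enrichment": "number",
        "n_permutations": "number"
      }
    },
    "de": {
      "required": { "n_selected": "number" }
    },
    "scan": {
      "required": {
        "expected_spacing": "number",
        "threshold": "number",
        "n_clusters": "number",
        "n_scaffolds_with_clusters": "number",
        "mean_hits_per_cluster": "number",
        "mean_enrichment": "number",
        "permutation_p_n_clusters": "number"
      }
    },
    "overlap": {
      "required": {
        "n_overlap": "number",
        "pct_of_selected": "number",
        "pct_of_truth": "number",
        "hypergeometric_p": "number"
      }
    }
  }
}
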