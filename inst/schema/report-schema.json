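{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "covnet pipeline report",
  "type": "object",
  "required": [
    "covnet_version",
    "settings",
    "data",
    "edge_comparison",
    "sparsity_curves",
    "hubs",
    "small_world",
    "permutation"
  ],
  "properties": {
    "covnet_version": { "type": "string" },
    "settings": {
      "type": "object",
      "required": ["grid", "hub_sparsity", "fdr_q", "n_random", "n_perm",
                   "ranking", "tail", "master_seed", "derived_seeds"],
      "properties": {
        "grid": { "type": "array", "items": { "type": "number" } },
        "hub_sparsity": { "type": "number" },
        "fdr_q": { "type": "number" },
        "n_random": { "type": "integer" },
        "n_perm": { "type": "integer" },
        "ranking": { "enum": ["signed", "absolute"] },
        "tail": { "enum": ["upper", "lower"] },
        "master_seed": { "type": "integer" },
        "derived_seeds": { "type": "object" }
      }
    },
    "data": {
      "type": "object",
      "required": ["n_subjects", "n_regions", "groups", "synthetic"]
    },
    "edge_comparison": {
      "type": "object",
      "required": ["n_edges", "n_fdr_significant", "n_increased", "n_decreased"]
    },
    "sparsity_curves": { "type": "array" },
    "hubs": { "type": "object" },
    "small_world": { "type": "object" },
    "permutation": {
      "type": "object",
      "required": ["global", "nodal_mean_p"]
    }
  }
}
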