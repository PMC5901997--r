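{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "epidiatom pipeline summary",
  "type": "object",
  "required": ["seed", "simulated", "channels", "bray_curtis", "nmds",
               "partitions", "mantel", "distance_comparison",
               "guild_profile"],
  "properties": {
    "seed": {"type": "integer"},
    "simulated": {"type": "boolean"},
    "channels": {
      "type": "object",
      "required": ["microscopy", "metabarcoding"]
    },
    "bray_curtis": {
      "type": "object",
      "required": ["mean_microscopy", "mean_metabarcoding"],
      "properties": {
        "mean_microscopy": {"type": "number", "minimum": 0, "maximum": 1},
        "mean_metabarcoding": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "nmds": {"type": "object", "required": ["microscopy", "metabarcoding"]},
    "partitions": {"type": "object",
                   "required": ["microscopy", "metabarcoding"]},
    "mantel": {
      "type": "object",
      "required": ["r", "r_squared", "p", "n_permutations"],
      "properties": {
        "r": {"type": "number", "minimum": -1, "maximum": 1},
        "r_squared": {"type": "number", "minimum": 0, "maximum": 1},
        "p": {"type": "number", "exclusiveMinimum": 0, "maximum": 1}
      }
    },
    "distance_comparison": {
      "type": "object",
      "required": ["mean_a", "mean_b", "t_statistic", "p_parametric",
                   "p_permutation", "n_a", "n_b"]
    },
    "cryptic": {
      "type": ["object", "null"],
      "required": ["threshold", "n_groups", "membership"]
    },
    "guild_profile": {"type": "array"}
  }
}
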