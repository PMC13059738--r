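{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "phagecode pipeline report",
  "type": "object",
  "required": ["tool", "seed", "parameters", "genomes", "crispr", "markers"],
  "properties": {
    "tool": {"const": "phagecode"},
    "seed": {"type": "integer"},
    "parameters": {
      "type": "object",
      "required": ["candidate_tables", "min_orf_len", "threshold_fraction",
                   "density_margin", "min_identity", "min_coverage"]
    },
    "genomes": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["id", "length", "topology", "gc_content",
                     "code_assessment"],
        "properties": {
          "code_assessment": {
            "type": "object",
            "required": ["tables", "disruption", "assigned_table"]
          }
        }
      }
    },
    "crispr": {"type": "object", "required": ["status"]},
    "markers": {"type": "object", "required": ["status"]}
  }
}
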