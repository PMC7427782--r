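{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "helixstates analysis report",
  "type": "object",
  "required": ["id", "chains", "comparisons", "provenance"],
  "properties": {
    "id": {"type": "string"},
    "chains": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["chain", "hbonds", "classification", "dihedrals",
                     "advance", "axes", "m2_offset3_bonds", "form_call"]
      }
    },
    "comparisons": {
      "type": ["object", "array"],
      "properties": {
        "rmsd_matrix": {"type": "array"},
        "displacements": {"type": "object"}
      }
    },
    "coordination": {"type": ["object", "array", "null"]},
    "provenance": {
      "type": "object",
      "required": ["input", "source_format", "tool", "version", "config",
                   "regions", "timestamp"]
    }
  }
}
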