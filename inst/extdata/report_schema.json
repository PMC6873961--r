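{
  "$comment": "Structure of a panelmips clinical report JSON",
  "type": "object",
  "required": ["sample_id", "n_matches", "variants"],
  "properties": {
    "sample_id": {"type": "string"},
    "n_matches": {"type": "integer"},
    "variants": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variant_id", "gene", "name", "coordinates", "vaf",
                     "evidence_score", "link", "evidence_items"],
        "properties": {
          "variant_id": {"type": "string"},
          "gene": {"type": "string"},
          "name": {"type": "string"},
          "coordinates": {"type": "string"},
          "vaf": {"type": "number"},
          "depth": {"type": "integer"},
          "evidence_score": {"type": "number"},
          "description": {"type": "string"},
          "assertions": {"type": "array", "items": {"type": "string"}},
          "link": {"type": "string"},
          "evidence_items": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id", "evidence_type", "evidence_level",
                           "trust_rating", "clinical_significance",
                           "disease", "citation", "link"]
            }
          }
        }
      }
    }
  }
}
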