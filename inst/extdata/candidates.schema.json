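{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "acrmine candidate report",
  "type": "object",
  "required": ["candidates"],
  "properties": {
    "candidates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": [
          "gene_id", "replicon_id", "candidate_class", "qualifies",
          "adjacent_marker", "orientation_ok", "has_dna_binding_domain",
          "association_count", "confidence_tier"
        ],
        "properties": {
          "gene_id": {"type": "string"},
          "replicon_id": {"type": "string"},
          "protein_length": {"type": "integer"},
          "families": {"type": "string"},
          "marker_families": {"type": ["string", "null"]},
          "marker_side": {"type": ["string", "null"]},
          "candidate_class": {"enum": ["acr_candidate", "aca_candidate"]},
          "qualifies": {"type": "boolean"},
          "size_ok": {"type": ["boolean", "null"]},
          "adjacent_marker": {"type": "boolean"},
          "orientation_ok": {"type": "boolean"},
          "has_dna_binding_domain": {"type": "boolean"},
          "association_count": {"type": "integer"},
          "fusion": {"type": "boolean"},
          "fusion_side": {"type": ["string", "null"]},
          "fusion_aca_start": {"type": ["integer", "null"]},
          "fusion_aca_end": {"type": ["integer", "null"]},
          "acr_remainder_length": {"type": ["integer", "null"]},
          "confidence_tier": {"enum": ["standard", "fusion_boosted"]}
        }
      }
    }
  }
}
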