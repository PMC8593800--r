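{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "midcross/scorecard/1.1",
  "title": "midcross screening score card",
  "type": "object",
  "required": ["schema_version", "session_id", "stage_id", "criterion_points",
               "total", "classification", "provenance"],
  "properties": {
    "schema_version": {"const": "1.1"},
    "session_id": {"type": ["string", "null"]},
    "stage_id": {"type": "integer", "minimum": 1, "maximum": 4},
    "criterion_points": {
      "type": "array", "minItems": 8, "maxItems": 8,
      "items": {"enum": [0, 1]}
    },
    "total": {"type": "integer", "minimum": 0, "maximum": 8},
    "classification": {"enum": ["no_pathology_indicated", "further_assessment_needed"],
      "description": "no_pathology_indicated iff total >= 4"},
    "provenance": {
      "type": "array", "minItems": 8, "maxItems": 8,
      "items": {"enum": ["gameplay", "observation", "automated"]}
    },
    "incomplete": {"type": "boolean"}
  }
}
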