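{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "midcross/notes/1.1",
  "title": "midcross observational notes record",
  "type": "object",
  "required": ["schema_version", "session_id", "recorder_role"],
  "properties": {
    "schema_version": {"const": "1.1"},
    "session_id": {"type": "string", "description": "must reference an existing session record"},
    "recorder_role": {"enum": ["occupational_therapist", "caretaker", "parent", "teacher", "guardian"]},
    "followed_instructions": {"type": ["boolean", "null"]},
    "maintained_visual_focus": {"type": ["boolean", "null"]},
    "gross_body_adjustments": {"type": ["boolean", "null"]},
    "verbal_cues_required": {"type": ["boolean", "null"]},
    "distance_pattern_observed": {"type": ["boolean", "null"],
      "description": "observer judgement: did misses worsen with the difficulty variable?"},
    "free_text": {"type": "string"},
    "completed_at": {"type": ["string", "null"], "description": "ISO-8601 UTC"}
  }
}
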