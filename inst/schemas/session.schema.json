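{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "midcross/session/1.1",
  "title": "midcross session record",
  "type": "object",
  "required": ["schema_version", "session_id", "child_id", "handedness",
               "stage_config", "events", "final_score", "rng_seed"],
  "properties": {
    "schema_version": {"const": "1.1"},
    "session_id": {"type": "string"},
    "child_id": {"type": "string", "description": "pseudonymous identifier; no personal data"},
    "handedness": {"enum": ["left", "right"]},
    "stage_config": {
      "type": "object",
      "required": ["stage_id", "duration_s", "x_min", "x_max"],
      "properties": {
        "stage_id": {"type": "integer", "minimum": 1, "maximum": 4},
        "x0": {"type": ["number", "null"]},
        "incr_dist": {"type": ["number", "null"]},
        "dist_var": {"type": ["number", "null"], "minimum": 0},
        "speed0": {"type": ["number", "null"], "exclusiveMinimum": 0},
        "incr_speed": {"type": ["number", "null"], "minimum": 0},
        "constant_speed": {"type": "number", "exclusiveMinimum": 0},
        "duration_s": {"type": "number", "exclusiveMinimum": 0},
        "x_min": {"type": "number"},
        "x_max": {"type": "number"}
      }
    },
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["index", "spawn_x", "spawn_time_s", "fall_speed",
                     "outcome", "score_after"],
        "properties": {
          "index": {"type": "integer", "minimum": 1},
          "spawn_x": {"type": "number"},
          "spawn_time_s": {"type": "number", "minimum": 0},
          "fall_speed": {"type": "number", "exclusiveMinimum": 0},
          "outcome": {"enum": ["caught", "missed"]},
          "catch_time_s": {"type": ["number", "null"]},
          "return_time_s": {"type": ["number", "null"]},
          "score_after": {"type": "integer", "minimum": 0}
        }
      }
    },
    "final_score": {"type": "integer", "minimum": 0},
    "balls_spawned": {"type": "integer", "minimum": 0},
    "balls_caught": {"type": "integer", "minimum": 0},
    "balls_missed": {"type": "integer", "minimum": 0},
    "clock_s": {"type": "number", "minimum": 0},
    "hat_x": {"type": "number"},
    "home_x": {"type": "number"},
    "rng_seed": {"type": "integer"},
    "started_at": {"type": ["string", "null"], "description": "ISO-8601 UTC"}
  }
}
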