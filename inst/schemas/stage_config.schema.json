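{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "midcross/stage_config/1.1",
  "title": "midcross run configuration file",
  "description": "YAML or JSON; stage parameters plus run settings for cmd_simulate",
  "type": "object",
  "required": ["stage_id"],
  "properties": {
    "stage_id": {"type": "integer", "minimum": 1, "maximum": 4},
    "x0": {"type": "number", "description": "starting distance (stages 1-3)"},
    "incr_dist": {"type": "number", "description": "incremental distance per point (stage 1)"},
    "dist_var": {"type": "number", "minimum": 0, "description": "spawn jitter half-width (stage 2)"},
    "speed0": {"type": "number", "exclusiveMinimum": 0, "description": "initial fall speed (stage 3)"},
    "incr_speed": {"type": "number", "minimum": 0, "description": "incremental fall speed per point (stage 3)"},
    "constant_speed": {"type": "number", "exclusiveMinimum": 0, "default": 2},
    "duration_s": {"type": "number", "exclusiveMinimum": 0, "default": 120},
    "handedness": {"enum": ["left", "right"], "default": "right"},
    "seed": {"type": "integer", "default": 1},
    "profile": {"enum": ["unimpaired", "impaired-mild", "impaired-severe"],
                "default": "unimpaired"}
  }
}
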