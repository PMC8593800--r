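{
  "schema_version": "1.0",
  "session_id": "legacy-01",
  "child_id": "child-42",
  "handedness": "right",
  "stage_config": {
    "stage_id": 1,
    "x0": 1,
    "incr_dist": 0.5,
    "constant_speed": 2,
    "duration_s": 120,
    "x_min": -7.5,
    "x_max": 7.5
  },
  "fall_speed": 2,
  "events": [
    {
      "index": 1,
      "spawn_x": 1,
      "spawn_time_s": 0,
      "outcome": "caught",
      "catch_time_s": 5,
      "return_time_s": 6.4,
      "score_after": 1
    },
    {
      "index": 2,
      "spawn_x": 1.5,
      "spawn_time_s": 6.4,
      "outcome": "missed",
      "catch_time_s": null,
      "return_time_s": null,
      "score_after": 1
    }
  ],
  "final_score": 1,
  "balls_spawned": 2,
  "balls_caught": 1,
  "balls_missed": 1,
  "clock_s": 120,
  "hat_x": -7.5,
  "home_x": -7.5,
  "rng_seed": 7,
  "started_at": "2026-01-10T09:00:00Z"
}
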