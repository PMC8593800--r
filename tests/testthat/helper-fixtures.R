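# shared fixtures, all built in code

# a deterministic player that reaches every ball (no lapses, no deficit)
perfect_player <- function() {
  player_model(hat_speed = 6, reaction_delay_s = 0.3, lapse_rate = 0,
               label = "perfect")
}

# a player that never responds at all
frozen_player <- function() {
  player_model(lapse_rate = 1, label = "frozen")
}

# a small complete valid session built by the engine
quick_session <- function(stage_id = 1, seed = 1, player = perfect_player(),
                          handedness = "right", ...) {
  run_session(default_stage_config(stage_id), handedness = handedness,
              player = player, seed = seed, ...)
}

# random-but-valid stage config for property sweeps; `duration_s` kept short
# so large sweeps stay cheap
random_stage_config <- function(stage_id = sample(1:4, 1),
                                duration_s = 30) {
  x0 <- stats::runif(1, -3, 3)
  switch(stage_id,
    stage_config(1, x0 = x0, incr_dist = stats::runif(1, 0, 1),
                 duration_s = duration_s),
    stage_config(2, x0 = x0, dist_var = stats::runif(1, 0, 2),
                 duration_s = duration_s),
    stage_config(3, x0 = x0, speed0 = stats::runif(1, 1, 3),
                 incr_speed = stats::runif(1, 0, 0.3),
                 duration_s = duration_s),
    stage_config(4, duration_s = duration_s)
  )
}

random_player <- function() {
  player_model(hat_speed = stats::runif(1, 3, 9),
               reaction_delay_s = stats::runif(1, 0, 1),
               lapse_rate = stats::runif(1, 0, 0.3),
               crossing_delay_s = stats::runif(1, 0, 3),
               crossing_penalty = stats::runif(1, 0, 0.3))
}

# synthetic gameplay stats with a chosen challenge/outcome vector
stats_from_vectors <- function(challenge, outcome, stage_id = 1L,
                               mean_gap = 6) {
  ev <- data.frame(spawn_x = challenge, challenge = challenge,
                   fall_speed = 2, outcome = outcome,
                   stringsAsFactors = FALSE)
  midcross:::gameplay_stats(
    balls_caught = sum(outcome == "caught"),
    balls_missed = sum(outcome == "missed"),
    mean_inter_ball_time_s = mean_gap, events = ev, stage_id = stage_id)
}

# complete favourable notes for a session id
favourable_notes <- function(session_id = "manual") {
  notes_record(session_id, "caretaker",
               followed_instructions = TRUE, maintained_visual_focus = TRUE,
               gross_body_adjustments = FALSE, verbal_cues_required = FALSE,
               distance_pattern_observed = FALSE)
}
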