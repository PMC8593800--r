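#' Engine timing and geometry parameters
#'
#' Mechanical constants of the headless game, kept separate from the stage
#' difficulty parameters. Balls spawn at height `y_top` (game units) above the
#' hat line and descend at the stage's fall speed, so a ball is in the air for
#' `y_top / fall_speed` seconds; with the defaults (10 units, speed 2) that is
#' a 5 s fall, giving an engaged player roughly 16-18 ball opportunities in a
#' 120 s session. A ball is caught when the hat centre is within
#' `catch_half_width` of the ball at the moment it reaches the hat line, and a
#' caught ball scores once the hat comes back within `return_tol` of the home
#' edge. After a miss the next ball spawns after `miss_respawn_pause_s`
#' seconds (an inter-trial pause during which the child withdraws the hat to
#' the home side); after a scored return the next ball spawns immediately.
#' All event times are quantised to the `dt` simulation grid so sessions are
#' exactly reproducible.
#'
#' @param dt Simulation time grid, seconds.
#' @param y_top Spawn height above the hat line, game units.
#' @param catch_half_width Half-width of the catch window, game units.
#' @param return_tol Distance from the home edge that counts as returned.
#' @param miss_respawn_pause_s Pause before respawn after a missed ball.
#' @return A list of class `midcross_engine`.
#' @export
engine_params <- function(dt = 0.02, y_top = 10, catch_half_width = 0.5,
                          return_tol = 0.25, miss_respawn_pause_s = 4) {
  stopifnot(is_scalar_number(dt), dt > 0,
            is_scalar_number(y_top), y_top > 0,
            is_scalar_number(catch_half_width), catch_half_width >= 0,
            is_scalar_number(return_tol), return_tol >= 0,
            is_scalar_number(miss_respawn_pause_s), miss_respawn_pause_s >= 0)
  structure(list(dt = dt, y_top = y_top, catch_half_width = catch_half_width,
                 return_tol = return_tol,
                 miss_respawn_pause_s = miss_respawn_pause_s),
            class = "midcross_engine")
}

# round a duration up to the simulation grid
snap_up <- function(x, dt) ceiling(x / dt - 1e-9) * dt

# config expressed in the canonical right-handed frame
canonical_config <- function(config, handedness) {
  if (handedness == "left" && !is.null(config$x0)) {
    config$x0 <- mirror_x(config$x0)
  }
  config
}

#' Simulate one game session
#'
#' Runs the serial ball loop of the game for the full session clock: spawn a
#' ball at the stage's rule (evaluated at the score after the last completed
#' return), let it fall while the player executes the movement plan from
#' [decide_response()], resolve catch or miss when the ball reaches the hat
#' line, and on a catch move the hat home to bank the point. The session is
#' deterministic given `(config, handedness, player, seed)`.
#'
#' Mechanics in detail: every ball is attempted from the home edge (the child
#' withdraws the hat between balls — after a return it is home by definition,
#' after a miss it comes back during the respawn pause), so every ball on the
#' contralateral side is a fresh midline challenge. Hat motion is constant
#' speed toward the plan's target, so each cycle has a closed-form timeline;
#' all times are rounded up to the engine `dt` grid, making the result
#' identical to a fixed-step simulation. A ball still in the air when the
#' clock reaches the duration is abandoned (spawned but neither caught nor
#' missed); a ball caught but not yet returned in time keeps its catch but
#' earns no point.
#'
#' Left-handed play is the mirror image of right-handed play: the engine
#' simulates in the canonical right-handed frame (negating `x0` for
#' left-handed configs) and negates all x-positions in the returned record.
#'
#' @param config A `midcross_stage`.
#' @param handedness `"right"` or `"left"`; decides the home side.
#' @param player A `midcross_player` driving the hat.
#' @param seed Integer seed; the single RNG source for the session (spawn
#'   jitter, lapses, refusals), recorded in the result for exact replay.
#' @param engine Engine constants from [engine_params()].
#' @param session_id,child_id Identifier strings (pseudonymous).
#' @param started_at Optional ISO-8601 timestamp string; left `NA` by default
#'   so identical inputs give byte-identical records.
#' @return A `midcross_session`: identifiers, the config, per-ball `events`
#'   (`index`, `spawn_x`, `spawn_time_s`, `fall_speed`, `outcome`,
#'   `catch_time_s`, `return_time_s`, `score_after`), `final_score`, counters
#'   (`balls_spawned`, `balls_caught`, `balls_missed`), `clock_s`, and the
#'   seed.
#' @examples
#' s <- run_session(default_stage_config(1), "right",
#'                  make_profile("unimpaired"), seed = 7)
#' s$final_score
#' @export
run_session <- function(config, handedness = c("right", "left"),
                        player = make_profile("unimpaired"), seed = 1L,
                        engine = engine_params(), session_id = NULL,
                        child_id = "child-01", started_at = NA_character_) {
  stopifnot(inherits(config, "midcross_stage"),
            inherits(player, "midcross_player"),
            inherits(engine, "midcross_engine"))
  handedness <- match.arg(handedness)
  if (!is_scalar_number(seed)) stop("`seed` must be a number", call. = FALSE)
  seed <- as.integer(seed)
  cfg <- canonical_config(config, handedness)
  dur <- cfg$duration_s
  dt <- engine$dt
  home <- cfg$x_min # canonical frame: home is always the left edge

  idx <- integer(0); sxs <- numeric(0); sts <- numeric(0); fss <- numeric(0)
  outc <- character(0); cts <- numeric(0); rts <- numeric(0); sca <- integer(0)

  score <- 0L
  spawned <- 0L
  t <- 0
  hat_end <- home

  with_seed(seed, {
    repeat {
      if (t >= dur - 1e-9) break
      sx <- spawn_position(cfg, score)
      fs <- ball_speed(cfg, score)
      spawned <- spawned + 1L
      fall <- snap_up(engine$y_top / fs, dt)
      arrive <- t + fall
      if (arrive > dur + 1e-9) break # in flight at the final whistle: abandoned

      plan <- decide_response(player, sx, home)
      move_t <- max(0, fall - plan$delay_s)
      reach <- abs(plan$target_x - home)
      moved <- min(plan$speed * move_t, reach)
      hat_arr <- home + sign(plan$target_x - home) * moved
      caught <- abs(hat_arr - sx) <= engine$catch_half_width + 1e-12

      idx <- c(idx, spawned); sxs <- c(sxs, sx); sts <- c(sts, t)
      fss <- c(fss, fs); outc <- c(outc, if (caught) "caught" else "missed")

      if (caught) {
        back <- max(0, abs(hat_arr - home) - engine$return_tol)
        ret <- arrive + snap_up(back / plan$speed, dt)
        if (ret > dur + 1e-9) {
          # caught but the clock ran out before the hat got home: no point
          cts <- c(cts, arrive); rts <- c(rts, NA_real_); sca <- c(sca, score)
          hat_end <- hat_arr - sign(hat_arr - home) *
            min(abs(hat_arr - home), plan$speed * max(0, dur - arrive))
          t <- dur
          break
        }
        score <- score + 1L
        cts <- c(cts, arrive); rts <- c(rts, ret); sca <- c(sca, score)
        t <- ret
        hat_end <- home
      } else {
        cts <- c(cts, NA_real_); rts <- c(rts, NA_real_); sca <- c(sca, score)
        t <- arrive + engine$miss_respawn_pause_s
        hat_end <- home
      }
    }
  })

  events <- data.frame(
    index = idx, spawn_x = sxs, spawn_time_s = sts, fall_speed = fss,
    outcome = outc, catch_time_s = cts, return_time_s = rts,
    score_after = sca, stringsAsFactors = FALSE
  )
  if (handedness == "left") {
    events$spawn_x <- mirror_x(events$spawn_x)
    hat_end <- mirror_x(hat_end)
    home <- mirror_x(home)
  }

  record <- structure(
    list(
      schema_version = MIDCROSS_SCHEMA_VERSION,
      session_id = session_id %||% sprintf("s%d-stage%d", seed, cfg$stage_id),
      child_id = child_id,
      handedness = handedness,
      stage_config = config,
      events = events,
      final_score = score,
      balls_spawned = spawned,
      balls_caught = sum(events$outcome == "caught"),
      balls_missed = sum(events$outcome == "missed"),
      clock_s = dur,
      hat_x = hat_end,
      home_x = home,
      rng_seed = seed,
      started_at = started_at
    ),
    class = "midcross_session"
  )
  validate_session(record)
  record
}

#' @export
print.midcross_session <- function(x, ...) {
  cat(sprintf(
    "<midcross session %s> child %s, stage %d, %s-handed, seed %d\n",
    x$session_id, x$child_id, x$stage_config$stage_id, x$handedness,
    x$rng_seed))
  cat(sprintf("  %d balls: %d caught, %d missed; final score %d in %g s\n",
              x$balls_spawned, x$balls_caught, x$balls_missed,
              x$final_score, x$clock_s))
  invisible(x)
}
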