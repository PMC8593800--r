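#' Stage configuration for the catching game
#'
#' Builds and validates the parameter set that defines one stage of the game.
#' The playfield is a horizontal axis from `x_min` to `x_max` (default
#' -7.5 to +7.5 game units) with the body midline at `x = 0`. Each of the four
#' stages uses a different rule to place falling balls:
#'
#' * **Stage 1** (assessment): first ball at the starting distance `x0`; each
#'   earned point moves the spawn point a further `incr_dist` units away, so
#'   spawn position is `x0 + incr_dist * score` (clipped to the playfield).
#'   A missed ball leaves the score, and hence the spawn point, unchanged.
#' * **Stage 2** (intervention, distance jitter): balls spawn uniformly in
#'   `x0 +/- dist_var`. With `x0 = 1.5` and `dist_var = 0.5` balls land
#'   between points 1 and 2.
#' * **Stage 3** (intervention, speed grading): balls always spawn at `x0`,
#'   but fall speed is `speed0 + incr_speed * score`, rising with each ball
#'   caught and returned.
#' * **Stage 4** (maintenance): balls spawn uniformly anywhere on the axis;
#'   speed is constant.
#'
#' Fall speed in stages 1, 2 and 4 is `constant_speed`. Session length is
#' fixed at `duration_s` seconds (default 120 — two minutes, chosen short so a
#' young child can hold concentration for a whole session).
#'
#' All distance parameters are interpreted in the right-handed frame (hat home
#' on the left edge, distances growing rightward across the midline); see
#' [run_session()] for how left-handed play mirrors the frame.
#'
#' @param stage_id Integer 1-4.
#' @param x0 Starting distance on the x-axis (stages 1-3).
#' @param incr_dist Incremental distance per point (stage 1).
#' @param dist_var Distance variance: half-width of the uniform spawn interval
#'   around `x0` (stage 2). Must be non-negative.
#' @param speed0 Initial fall speed in game units/second (stage 3).
#' @param incr_speed Incremental fall speed per point (stage 3).
#' @param constant_speed Fall speed for stages 1, 2 and 4 (game units/second).
#' @param duration_s Session duration in seconds.
#' @param x_min,x_max Playfield bounds; must be symmetric about the midline.
#' @return An object of class `midcross_stage`.
#' @seealso [default_stage_config()], [spawn_position()], [ball_speed()]
#' @examples
#' cfg <- stage_config(2, x0 = 1.5, dist_var = 0.5)
#' spawn_position(cfg, score = 0) # somewhere in [1, 2]
#' @export
stage_config <- function(stage_id, x0 = NULL, incr_dist = NULL, dist_var = NULL,
                         speed0 = NULL, incr_speed = NULL, constant_speed = 2,
                         duration_s = 120, x_min = -7.5, x_max = 7.5) {
  if (!is_scalar_number(stage_id) || !(stage_id %in% 1:4)) {
    stop("`stage_id` must be one of 1, 2, 3, 4", call. = FALSE)
  }
  stage_id <- as.integer(stage_id)
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be a positive number of seconds", call. = FALSE)
  }
  if (!is_scalar_number(x_min) || !is_scalar_number(x_max) ||
      !(x_min < 0 && 0 < x_max)) {
    stop("playfield bounds must satisfy x_min < 0 < x_max", call. = FALSE)
  }
  if (abs(x_min + x_max) > 1e-9) {
    stop("playfield must be symmetric about the midline: x_min = -x_max",
         call. = FALSE)
  }

  need <- function(value, name) {
    if (is.null(value)) {
      stop(sprintf("stage %d requires parameter `%s`", stage_id, name),
           call. = FALSE)
    }
    if (!is_scalar_number(value)) {
      stop(sprintf("`%s` must be a finite number", name), call. = FALSE)
    }
    value
  }
  check_x0 <- function(x0) {
    if (x0 < x_min || x0 > x_max) {
      stop("`x0` must lie within the playfield bounds", call. = FALSE)
    }
    x0
  }

  if (stage_id == 1L) {
    x0 <- check_x0(need(x0, "x0"))
    incr_dist <- need(incr_dist, "incr_dist")
  } else if (stage_id == 2L) {
    x0 <- check_x0(need(x0, "x0"))
    dist_var <- need(dist_var, "dist_var")
    if (dist_var < 0) stop("`dist_var` must be >= 0", call. = FALSE)
  } else if (stage_id == 3L) {
    x0 <- check_x0(need(x0, "x0"))
    speed0 <- need(speed0, "speed0")
    incr_speed <- need(incr_speed, "incr_speed")
    if (speed0 <= 0) stop("`speed0` must be > 0", call. = FALSE)
    if (incr_speed < 0) stop("`incr_speed` must be >= 0", call. = FALSE)
  }
  if (stage_id != 3L) {
    if (!is_scalar_number(constant_speed) || constant_speed <= 0) {
      stop("`constant_speed` must be > 0", call. = FALSE)
    }
  }

  structure(
    list(stage_id = stage_id, x0 = x0, incr_dist = incr_dist,
         dist_var = dist_var, speed0 = speed0, incr_speed = incr_speed,
         constant_speed = constant_speed, duration_s = duration_s,
         x_min = x_min, x_max = x_max),
    class = "midcross_stage"
  )
}

#' Default configuration for each stage
#'
#' The documented defaults used throughout the package: stage 1 starts one
#' unit past the midline and steps half a unit per point; stage 2 uses the
#' worked example values (start 1.5, variance 0.5); stage 3 starts at 1.5
#' units with fall speed 2 units/s rising by 0.1 per point; stage 4 needs no
#' distance input. All stages use a 2 game-unit/s constant fall speed where
#' speed is constant, and a 120 s session.
#'
#' @param stage_id Integer 1-4.
#' @return A `midcross_stage` object.
#' @export
default_stage_config <- function(stage_id) {
  if (!is_scalar_number(stage_id) || !(stage_id %in% 1:4)) {
    stop("`stage_id` must be one of 1, 2, 3, 4", call. = FALSE)
  }
  switch(as.integer(stage_id),
    stage_config(1, x0 = 1.0, incr_dist = 0.5),
    stage_config(2, x0 = 1.5, dist_var = 0.5),
    stage_config(3, x0 = 1.5, speed0 = 2, incr_speed = 0.1),
    stage_config(4)
  )
}

#' @export
print.midcross_stage <- function(x, ...) {
  cat(sprintf("<midcross stage %d> playfield [%g, %g], duration %g s\n",
              x$stage_id, x$x_min, x$x_max, x$duration_s))
  pars <- c(x0 = x$x0, incr_dist = x$incr_dist, dist_var = x$dist_var,
            speed0 = x$speed0, incr_speed = x$incr_speed)
  pars <- pars[!vapply(pars, is.null, logical(1))]
  if (length(pars)) {
    cat("  ", paste(names(pars), unlist(pars), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  if (x$stage_id != 3L) cat("  fall speed (constant):", x$constant_speed, "\n")
  invisible(x)
}

#' Spawn position of the next ball
#'
#' Evaluates the stage's distance rule at the current score. Stage 1 gives
#' `x0 + incr_dist * score`; stage 2 draws uniformly from `x0 +/- dist_var`;
#' stage 3 always returns `x0`; stage 4 draws uniformly over the whole
#' playfield. Results are clipped to the playfield bounds. Stages 2 and 4
#' consume one draw from R's random number stream, so seed (or let
#' [run_session()] seed) before calling for reproducible positions.
#'
#' @param config A `midcross_stage`.
#' @param score Current score (balls caught and returned so far).
#' @return Spawn x-position in game units, inside the playfield.
#' @export
spawn_position <- function(config, score) {
  stopifnot(inherits(config, "midcross_stage"))
  if (!is_scalar_number(score) || score < 0 || score != round(score)) {
    stop("`score` must be a non-negative integer", call. = FALSE)
  }
  x <- switch(config$stage_id,
    config$x0 + config$incr_dist * score,
    config$x0 + stats::runif(1, -config$dist_var, config$dist_var),
    config$x0,
    stats::runif(1, config$x_min, config$x_max)
  )
  min(max(x, config$x_min), config$x_max)
}

#' Fall speed of the next ball
#'
#' Constant in stages 1, 2 and 4; in stage 3 the speed is
#' `speed0 + incr_speed * score`, so each caught-and-returned ball makes the
#' next one fall faster.
#'
#' @inheritParams spawn_position
#' @return Fall speed in game units/second (always positive).
#' @export
ball_speed <- function(config, score) {
  stopifnot(inherits(config, "midcross_stage"))
  if (!is_scalar_number(score) || score < 0 || score != round(score)) {
    stop("`score` must be a non-negative integer", call. = FALSE)
  }
  sp <- if (config$stage_id == 3L) {
    config$speed0 + config$incr_speed * score
  } else {
    config$constant_speed
  }
  if (sp <= 0) stop("configured fall speed is not positive", call. = FALSE)
  sp
}

#' Starting (home) position of the hat
#'
#' The hat starts on the side opposite the child's dominant hand so the very
#' first reach crosses the midline: a right-handed child starts on the left
#' edge, a left-handed child on the right edge. This is also the home side the
#' hat must be returned to before a point is scored.
#'
#' @param handedness `"right"` or `"left"`.
#' @param config A `midcross_stage` (supplies the playfield bounds).
#' @return Home x-position in game units.
#' @export
initial_hat_position <- function(handedness = c("right", "left"),
                                 config = default_stage_config(1)) {
  handedness <- match.arg(handedness)
  stopifnot(inherits(config, "midcross_stage"))
  if (handedness == "right") config$x_min else config$x_max
}

#' Mirror a position across the midline
#'
#' The game's difficulty rules are written in the right-handed frame;
#' left-handed play is its mirror image. `mirror_x` is the frame change:
#' negation about the midline at 0 (an involution with 0 as fixed point).
#'
#' @param x Position(s) in game units.
#' @return `-x`.
#' @export
mirror_x <- function(x) -x
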