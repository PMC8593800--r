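#' Parametric simulated child player
#'
#' The engine is driven by a simple behavioural model of a child operating the
#' slider: on each new ball the player waits a reaction delay, then moves the
#' hat toward the ball at a maximum lateral speed. Two mechanisms, both off by
#' default, reproduce the clinical picture of midline-crossing inhibition —
#' hesitancy and avoidance when a reach must pass the body midline:
#'
#' * `crossing_delay_s`: extra hesitation added to the reaction delay whenever
#'   the required movement crosses `x = 0`;
#' * `crossing_penalty`: per-game-unit probability weight of refusing to cross
#'   at all. For a ball `d` units past the midline the player refuses with
#'   probability `min(1, crossing_penalty * d)` and stops at the midline —
#'   the "uses the left hand for activities on the left side" avoidance
#'   pattern.
#'
#' Independently, `lapse_rate` is the probability of ignoring a ball entirely
#' (attention lapse), modelling ordinary distraction in young children.
#'
#' With `crossing_delay_s = 0` and `crossing_penalty = 0` the model reduces
#' exactly to the unimpaired player.
#'
#' @param hat_speed Maximum lateral hat speed, game units/second.
#' @param reaction_delay_s Delay before responding to a new ball, seconds.
#' @param lapse_rate Probability in \[0, 1\] of ignoring a ball.
#' @param crossing_delay_s Extra hesitation (seconds) when the reach crosses
#'   the midline. Non-negative.
#' @param crossing_penalty Refusal-probability weight per game unit of
#'   midline overshoot, in \[0, 1\].
#' @param label Free-text label carried along for reporting.
#' @return An object of class `midcross_player`.
#' @seealso [make_profile()], [decide_response()], [run_session()]
#' @export
player_model <- function(hat_speed = 6, reaction_delay_s = 0.3,
                         lapse_rate = 0.01, crossing_delay_s = 0,
                         crossing_penalty = 0, label = "custom") {
  if (!is_scalar_number(hat_speed) || hat_speed <= 0) {
    stop("`hat_speed` must be > 0", call. = FALSE)
  }
  if (!is_scalar_number(reaction_delay_s) || reaction_delay_s < 0) {
    stop("`reaction_delay_s` must be >= 0", call. = FALSE)
  }
  if (!is_scalar_number(lapse_rate) || lapse_rate < 0 || lapse_rate > 1) {
    stop("`lapse_rate` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(crossing_delay_s) || crossing_delay_s < 0) {
    stop("`crossing_delay_s` must be >= 0", call. = FALSE)
  }
  if (!is_scalar_number(crossing_penalty) || crossing_penalty < 0 ||
      crossing_penalty > 1) {
    stop("`crossing_penalty` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(hat_speed = hat_speed, reaction_delay_s = reaction_delay_s,
         lapse_rate = lapse_rate, crossing_delay_s = crossing_delay_s,
         crossing_penalty = crossing_penalty, label = label),
    class = "midcross_player"
  )
}

# Severity-1 deficit constants, fixed once by the calibration run shipped in
# inst/scripts/calibrate_profiles.R (see the methods vignette).
.impaired_crossing_delay <- 3.0   # s of hesitation at full severity
.impaired_crossing_penalty <- 0.15 # refusal weight per unit at full severity

#' Standard player profiles
#'
#' `make_profile("unimpaired")` returns the reference child: hat speed
#' 6 units/s, 0.3 s reaction delay, 1% attention lapses, no crossing deficit.
#' `make_profile("impaired", severity)` scales the two deficit parameters
#' linearly with `severity` in \[0, 1\]: hesitation `3.0 * severity` seconds
#' and refusal weight `0.15 * severity` per game unit. At `severity = 0` the
#' impaired profile is identical to the unimpaired one.
#'
#' The defaults were calibrated once (script in
#' `system.file("scripts", "calibrate_profiles.R", package = "midcross")`)
#' so that the score-card thresholds sit between the two populations, then
#' frozen; they are test instruments, not validated child models.
#'
#' @param kind `"unimpaired"` or `"impaired"`.
#' @param severity Deficit severity in \[0, 1\]; ignored for `"unimpaired"`.
#' @return A `midcross_player`.
#' @examples
#' identical(unclass(make_profile("impaired", severity = 0))[1:5],
#'           unclass(make_profile("unimpaired"))[1:5])
#' @export
make_profile <- function(kind = c("unimpaired", "impaired"), severity = 1) {
  kind <- match.arg(kind)
  if (!is_scalar_number(severity) || severity < 0 || severity > 1) {
    stop("`severity` must be in [0, 1]", call. = FALSE)
  }
  if (kind == "unimpaired") {
    player_model(label = "unimpaired")
  } else {
    player_model(crossing_delay_s = .impaired_crossing_delay * severity,
                 crossing_penalty = .impaired_crossing_penalty * severity,
                 label = sprintf("impaired (severity %.2f)", severity))
  }
}

#' Look up a named player profile
#'
#' Presets addressable from the command line and config files:
#' `"unimpaired"`, `"impaired-mild"` (severity 0.5) and `"impaired-severe"`
#' (severity 1).
#'
#' @param name Preset name.
#' @return A `midcross_player`.
#' @export
profile_by_name <- function(name) {
  switch(name,
    "unimpaired" = make_profile("unimpaired"),
    "impaired-mild" = make_profile("impaired", severity = 0.5),
    "impaired-severe" = make_profile("impaired", severity = 1),
    stop(sprintf("unknown profile '%s' (use unimpaired, impaired-mild or impaired-severe)",
                 name), call. = FALSE)
  )
}

#' Plan the player's response to a falling ball
#'
#' Draws the stochastic parts of the response (attention lapse; refusal to
#' cross) from R's random number stream and returns the movement plan the
#' engine executes: a target x, a start delay and the movement speed. An
#' unimpaired player heads for the ball after the reaction delay. An impaired
#' player facing a midline-crossing reach adds `crossing_delay_s` of
#' hesitation and, with probability `min(1, crossing_penalty * |ball_x|)`,
#' refuses to cross and stops at the midline. A lapsed player does not move.
#'
#' @param player A `midcross_player`.
#' @param ball_x Spawn x-position of the ball.
#' @param hat_x Current hat position (the reach starts here).
#' @return A list with `target_x`, `delay_s`, `speed`, `lapsed`, `refused`,
#'   `crossing` (whether the reach crosses the midline).
#' @export
decide_response <- function(player, ball_x, hat_x) {
  stopifnot(inherits(player, "midcross_player"))
  lapsed <- stats::runif(1) < player$lapse_rate
  crossing <- (hat_x < 0 && ball_x > 0) || (hat_x > 0 && ball_x < 0)
  delay <- player$reaction_delay_s +
    if (crossing) player$crossing_delay_s else 0
  refused <- FALSE
  if (!lapsed && crossing && player$crossing_penalty > 0) {
    p_refuse <- min(1, player$crossing_penalty * abs(ball_x))
    refused <- stats::runif(1) < p_refuse
  }
  target <- if (lapsed) hat_x else if (refused) 0 else ball_x
  list(target_x = target, delay_s = delay, speed = player$hat_speed,
       lapsed = lapsed, refused = refused, crossing = crossing)
}

#' @export
print.midcross_player <- function(x, ...) {
  cat(sprintf(
    "<midcross player: %s> speed %g u/s, reaction %g s, lapse %.3f, crossing delay %g s, penalty %.3f/u\n",
    x$label, x$hat_speed, x$reaction_delay_s, x$lapse_rate,
    x$crossing_delay_s, x$crossing_penalty))
  invisible(x)
}
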