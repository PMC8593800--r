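#' Gameplay statistics for the score card
#'
#' Reduces a session record to the quantities the first half of the score
#' card is computed from: balls caught, balls missed, the average time between
#' balls (mean gap between successive spawn times, in seconds), and the
#' per-ball table used by the miss-versus-challenge pattern test. The
#' challenge of a ball is the stage's difficulty variable: for stages 1, 2
#' and 4 the spawn distance measured from the midline into the side opposite
#' the child's dominant hand (positive = across the midline), and for stage 3
#' the fall speed.
#'
#' @param session A `midcross_session`.
#' @return A `midcross_stats` list: `balls_caught`, `balls_missed`,
#'   `mean_inter_ball_time_s` (`NA` with `timing_defined = FALSE` when fewer
#'   than two balls were spawned), `events` (spawn_x, challenge, fall_speed,
#'   outcome), `stage_id`, `handedness`, `n_events`.
#' @export
extract_stats <- function(session) {
  stopifnot(inherits(session, "midcross_session"))
  ev <- session$events
  n <- nrow(ev)
  timing_defined <- n >= 2
  gaps <- if (timing_defined) diff(ev$spawn_time_s) else numeric(0)
  side <- if (session$handedness == "right") 1 else -1
  challenge <- if (session$stage_config$stage_id == 3L) {
    ev$fall_speed
  } else {
    side * ev$spawn_x
  }
  structure(
    list(
      balls_caught = sum(ev$outcome == "caught"),
      balls_missed = sum(ev$outcome == "missed"),
      mean_inter_ball_time_s = if (timing_defined) mean(gaps) else NA_real_,
      timing_defined = timing_defined,
      events = data.frame(spawn_x = ev$spawn_x, challenge = challenge,
                          fall_speed = ev$fall_speed, outcome = ev$outcome,
                          stringsAsFactors = FALSE),
      stage_id = session$stage_config$stage_id,
      handedness = session$handedness,
      session_id = session$session_id,
      n_events = n
    ),
    class = "midcross_stats"
  )
}

# allow tests / batch tools to build stats without an engine run
gameplay_stats <- function(balls_caught, balls_missed,
                           mean_inter_ball_time_s = NA_real_,
                           events = NULL, stage_id = 1L,
                           handedness = "right", session_id = "manual") {
  structure(
    list(balls_caught = balls_caught, balls_missed = balls_missed,
         mean_inter_ball_time_s = mean_inter_ball_time_s,
         timing_defined = !is.na(mean_inter_ball_time_s),
         events = events %||% data.frame(spawn_x = numeric(0),
                                         challenge = numeric(0),
                                         fall_speed = numeric(0),
                                         outcome = character(0)),
         stage_id = as.integer(stage_id), handedness = handedness,
         session_id = session_id,
         n_events = if (is.null(events)) 0L else nrow(events)),
    class = "midcross_stats"
  )
}

#' Gameplay criteria 1-3
#'
#' The three score-card criteria computed from gameplay telemetry, with the
#' published thresholds taken as strict inequalities (the boundary value earns
#' no point):
#'
#' 1. balls caught `> 14`;
#' 2. balls missed `< 4`;
#' 3. average time between balls `< 7.5` seconds.
#'
#' When session timing is undefined (fewer than two balls) criterion 3 scores
#' 0 and the result carries `timing_defined = FALSE` as an attribute.
#'
#' @param stats A `midcross_stats` (from [extract_stats()]).
#' @return Integer vector of three 0/1 points.
#' @export
score_gameplay_criteria <- function(stats) {
  stopifnot(inherits(stats, "midcross_stats"))
  p3 <- if (isTRUE(stats$timing_defined)) {
    as.integer(stats$mean_inter_ball_time_s < 7.5)
  } else 0L
  pts <- c(as.integer(stats$balls_caught > 14),
           as.integer(stats$balls_missed < 4),
           p3)
  attr(pts, "timing_defined") <- isTRUE(stats$timing_defined)
  pts
}

#' Miss-versus-challenge pattern test (criterion 4)
#'
#' Criterion 4 asks whether misses show a pattern in the stage's difficulty
#' variable — for the assessment stage, whether the child missed more as the
#' spawn distance across the midline increased (the signature of
#' midline-crossing inhibition). The test statistic is the point-biserial
#' correlation between the per-ball challenge (contralateral spawn distance
#' for stages 1, 2, 4; fall speed for stage 3) and the miss indicator; its
#' p-value comes from a seeded permutation null obtained by shuffling the
#' miss labels, `p = (1 + #{r_perm >= r_obs}) / (B + 1)` (one-sided, since
#' only difficulty-increasing miss patterns are clinically meaningful).
#' A pattern is declared when the correlation is positive and `p < 0.05`;
#' the score-card point is awarded when *no* pattern is found.
#'
#' Degenerate sessions (fewer than two balls, all balls the same outcome, or
#' a constant challenge) carry no evidence of a pattern: the test returns
#' `pattern = FALSE`, `p_value = 1`.
#'
#' @param stats A `midcross_stats`.
#' @param n_permutations Number of label permutations `B`.
#' @param seed Seed for the permutation draw.
#' @return List with `pattern` (logical), `p_value`, `statistic` (the
#'   observed correlation) and `n_permutations`.
#' @export
detect_distance_pattern <- function(stats, n_permutations = 999, seed = 1L) {
  stopifnot(inherits(stats, "midcross_stats"))
  ev <- stats$events
  miss <- as.integer(ev$outcome == "missed")
  ch <- ev$challenge
  degenerate <- nrow(ev) < 2 || length(unique(miss)) < 2 ||
    isTRUE(all(abs(ch - ch[1]) < 1e-12))
  if (degenerate) {
    return(list(pattern = FALSE, p_value = 1, statistic = NA_real_,
                n_permutations = as.integer(n_permutations)))
  }
  r_obs <- stats::cor(ch, miss)
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_permutations), function(i) {
      stats::cor(ch, sample(miss))
    }, numeric(1))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_permutations + 1)
    list(pattern = r_obs > 0 && p < 0.05, p_value = p, statistic = r_obs,
         n_permutations = as.integer(n_permutations))
  })
}

#' Build the 8-criterion screening score card
#'
#' Combines the three gameplay criteria, the miss-pattern criterion, and the
#' four observational criteria from the caretaker's notes into the score
#' card. A point is awarded per satisfied criterion; a child scoring a total
#' of at least 4 points is classified `no_pathology_indicated`, otherwise
#' `further_assessment_needed`. The criteria are designed to be read together
#' — the classification is a screen, not a diagnosis.
#'
#' Criterion 4 ("no pattern of misses in the difficulty variable") is
#' observational by default, read from the notes field
#' `distance_pattern_observed`; with `use_automated_pattern = TRUE` it is
#' computed from the gameplay data by [detect_distance_pattern()] instead.
#' The provenance of every criterion (gameplay / observation / automated) is
#' recorded on the card. Criteria 5-8 award their point when the notes report
#' that instructions were followed, visual focus was maintained, no gross
#' body adjustments were seen and no verbal cues were required. When notes
#' are missing the observational criteria score 0 and the card is flagged
#' incomplete.
#'
#' @param stats A `midcross_stats`.
#' @param notes A `midcross_notes` record, or `NULL` if none were taken.
#' @param use_automated_pattern Compute criterion 4 from gameplay data
#'   instead of the notes entry.
#' @param n_permutations,seed Passed to [detect_distance_pattern()] when the
#'   automated criterion 4 is used.
#' @return A `midcross_card`: `criterion_points` (eight 0/1 integers),
#'   `total`, `classification`, `stage_id`, `provenance` (length 8),
#'   `session_id`, `incomplete` flag, and the pattern-test result when
#'   computed.
#' @export
score_card <- function(stats, notes = NULL, use_automated_pattern = FALSE,
                       n_permutations = 999, seed = 1L) {
  stopifnot(inherits(stats, "midcross_stats"))
  if (!is.null(notes)) stopifnot(inherits(notes, "midcross_notes"))

  p123 <- score_gameplay_criteria(stats)
  incomplete <- !attr(p123, "timing_defined")
  provenance <- rep("gameplay", 3)
  pattern_test <- NULL

  if (use_automated_pattern) {
    pattern_test <- detect_distance_pattern(stats, n_permutations, seed)
    p4 <- as.integer(!pattern_test$pattern)
    provenance <- c(provenance, "automated")
  } else if (!is.null(notes) && !is.na(notes$distance_pattern_observed)) {
    p4 <- as.integer(!notes$distance_pattern_observed)
    provenance <- c(provenance, "observation")
  } else {
    p4 <- 0L
    provenance <- c(provenance, "observation")
    incomplete <- TRUE
  }

  obs_point <- function(value, favourable_when) {
    if (is.null(notes) || is.na(value)) {
      incomplete <<- TRUE
      0L
    } else {
      as.integer(value == favourable_when)
    }
  }
  p5 <- obs_point(if (is.null(notes)) NA else notes$followed_instructions, TRUE)
  p6 <- obs_point(if (is.null(notes)) NA else notes$maintained_visual_focus, TRUE)
  p7 <- obs_point(if (is.null(notes)) NA else notes$gross_body_adjustments, FALSE)
  p8 <- obs_point(if (is.null(notes)) NA else notes$verbal_cues_required, FALSE)
  provenance <- c(provenance, rep("observation", 4))

  points <- as.integer(c(p123, p4, p5, p6, p7, p8))
  new_score_card(points, stage_id = stats$stage_id,
                 provenance = provenance, session_id = stats$session_id,
                 incomplete = incomplete, pattern_test = pattern_test)
}

# low-level constructor (also used when enumerating criterion vectors)
new_score_card <- function(points, stage_id = 1L,
                           provenance = c(rep("gameplay", 3),
                                          rep("observation", 5)),
                           session_id = NA_character_, incomplete = FALSE,
                           pattern_test = NULL) {
  points <- as.integer(points)
  if (length(points) != 8 || any(!points %in% c(0L, 1L))) {
    stop("a score card has exactly 8 binary criterion points", call. = FALSE)
  }
  if (length(provenance) != 8 ||
      !all(provenance %in% c("gameplay", "observation", "automated"))) {
    stop("`provenance` must give one of gameplay/observation/automated per criterion",
         call. = FALSE)
  }
  total <- sum(points)
  structure(
    list(criterion_points = points, total = total,
         classification = classify_total(total),
         stage_id = as.integer(stage_id), provenance = provenance,
         session_id = session_id, incomplete = incomplete,
         pattern_test = pattern_test),
    class = "midcross_card"
  )
}

#' Screening classification from a score-card total
#'
#' A total of at least 4 of the 8 points indicates no midline-crossing
#' pathology; below that the child should be assessed further.
#'
#' @param total Integer total in 0-8.
#' @return `"no_pathology_indicated"` or `"further_assessment_needed"`.
#' @export
classify_total <- function(total) {
  if (!is_scalar_number(total) || total < 0 || total > 8 ||
      total != round(total)) {
    stop("`total` must be an integer in 0..8", call. = FALSE)
  }
  if (total >= 4) "no_pathology_indicated" else "further_assessment_needed"
}

#' @export
print.midcross_card <- function(x, ...) {
  labels <- c("balls caught > 14", "balls missed < 4",
              "avg time between balls < 7.5 s", "no miss-distance pattern",
              "followed instructions", "maintained visual focus",
              "no gross body adjustments", "no verbal cues")
  cat(sprintf("<midcross score card> session %s, stage %d%s\n",
              x$session_id, x$stage_id,
              if (x$incomplete) " (incomplete)" else ""))
  for (i in 1:8) {
    cat(sprintf("  %d. [%s] %-32s (%s)\n", i,
                if (x$criterion_points[i] == 1L) "x" else " ",
                labels[i], x$provenance[i]))
  }
  cat(sprintf("  total %d/8 -> %s\n", x$total, x$classification))
  invisible(x)
}
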