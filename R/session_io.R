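#' @name session_io
#' @title Telehealth wire formats
#' @description
#' Sessions, notes and score cards travel between the home and the therapist
#' as versioned JSON documents (schemas in `inst/schemas/`); score cards and
#' dashboard tables also export as flat CSV (comma separated, UTF-8, header
#' row). Every reader validates the record invariants and rejects unknown
#' schema versions; records written by schema version 1.0 (which stored one
#' fall speed per session instead of per ball) are migrated on read.
NULL

MIDCROSS_SCHEMA_VERSION <- "1.1"

RECORDER_ROLES <- c("occupational_therapist", "caretaker", "parent",
                    "teacher", "guardian")

#' Observational notes record
#'
#' The structured notes page a caretaker (or therapist) completes after each
#' stage. The four core booleans mirror the observational rows of the score
#' card; `distance_pattern_observed` is the observer's judgement for
#' criterion 4 (did misses worsen as the difficulty variable increased?).
#' Missing booleans are representable — the record is then flagged incomplete
#' rather than rejected, since a partially filled page still carries
#' information.
#'
#' @param session_id Id of the session the notes describe.
#' @param recorder_role One of occupational_therapist, caretaker, parent,
#'   teacher, guardian.
#' @param followed_instructions Did the child follow instructions?
#' @param maintained_visual_focus Did the child keep visual focus on the ball?
#' @param gross_body_adjustments Were gross body adjustments (trunk rotation
#'   etc.) observed?
#' @param verbal_cues_required Were verbal cues needed to prompt the reach?
#' @param distance_pattern_observed Did misses appear to increase with the
#'   difficulty variable? (`NA` if not judged.)
#' @param free_text Free-form observations.
#' @param completed_at ISO-8601 timestamp string, or `NA`.
#' @return A `midcross_notes` object (with an `incomplete` field).
#' @export
notes_record <- function(session_id, recorder_role = "caretaker",
                         followed_instructions = NA,
                         maintained_visual_focus = NA,
                         gross_body_adjustments = NA,
                         verbal_cues_required = NA,
                         distance_pattern_observed = NA,
                         free_text = "", completed_at = NA_character_) {
  if (!is.character(session_id) || length(session_id) != 1L) {
    stop("`session_id` must be a string", call. = FALSE)
  }
  if (!recorder_role %in% RECORDER_ROLES) {
    stop(sprintf("`recorder_role` must be one of: %s",
                 paste(RECORDER_ROLES, collapse = ", ")), call. = FALSE)
  }
  for (nm in c("followed_instructions", "maintained_visual_focus",
               "gross_body_adjustments", "verbal_cues_required",
               "distance_pattern_observed")) {
    v <- get(nm)
    if (!is_flag(v)) stop(sprintf("`%s` must be TRUE, FALSE or NA", nm),
                          call. = FALSE)
  }
  core <- c(followed_instructions, maintained_visual_focus,
            gross_body_adjustments, verbal_cues_required)
  structure(
    list(schema_version = MIDCROSS_SCHEMA_VERSION, session_id = session_id,
         recorder_role = recorder_role,
         followed_instructions = followed_instructions,
         maintained_visual_focus = maintained_visual_focus,
         gross_body_adjustments = gross_body_adjustments,
         verbal_cues_required = verbal_cues_required,
         distance_pattern_observed = distance_pattern_observed,
         free_text = free_text, completed_at = completed_at,
         incomplete = anyNA(core)),
    class = "midcross_notes"
  )
}

#' Synthetic notes matching a simulated population
#'
#' Convenience generator pairing simulated sessions with observational notes:
#' the `"favorable"` template reports a fully cooperative, focused child with
#' no compensation behaviours; `"unfavorable"` reports the observable
#' phenotype of midline-crossing difficulty (trunk rotation, lost focus,
#' verbal prompting, misses worsening with distance). Deterministic; intended
#' for simulation studies, not clinical use.
#'
#' @param session A `midcross_session` the notes should reference.
#' @param template `"favorable"` or `"unfavorable"`.
#' @return A complete `midcross_notes`.
#' @export
synthetic_notes <- function(session, template = c("favorable", "unfavorable")) {
  stopifnot(inherits(session, "midcross_session"))
  template <- match.arg(template)
  fav <- template == "favorable"
  notes_record(
    session_id = session$session_id, recorder_role = "caretaker",
    followed_instructions = fav, maintained_visual_focus = fav,
    gross_body_adjustments = !fav, verbal_cues_required = !fav,
    distance_pattern_observed = !fav,
    free_text = if (fav) "engaged throughout" else
      "rotated trunk to avoid crossing; needed prompting"
  )
}

# ---------------------------------------------------------------------------
# validation

validate_session <- function(x) {
  fail <- function(field, why) {
    stop(sprintf("invalid session record: field '%s' %s", field, why),
         call. = FALSE)
  }
  for (f in c("schema_version", "session_id", "child_id", "handedness",
              "stage_config", "events", "final_score", "rng_seed")) {
    if (is.null(x[[f]])) fail(f, "is missing")
  }
  if (!x$handedness %in% c("left", "right")) fail("handedness", "must be left or right")
  cfg <- x$stage_config
  ev <- x$events
  if (!is.data.frame(ev)) fail("events", "must be a table")
  if (nrow(ev)) {
    if (!all(ev$outcome %in% c("caught", "missed"))) {
      fail("events$outcome", "must be caught or missed")
    }
    if (is.unsorted(ev$spawn_time_s)) {
      fail("events$spawn_time_s", "must be ordered in time")
    }
    if (any(ev$spawn_x < cfg$x_min - 1e-9 | ev$spawn_x > cfg$x_max + 1e-9)) {
      fail("events$spawn_x", "must lie within the playfield")
    }
    if (any(ev$fall_speed <= 0)) fail("events$fall_speed", "must be positive")
    times <- c(ev$spawn_time_s, ev$catch_time_s, ev$return_time_s)
    if (any(times > cfg$duration_s + 1e-9, na.rm = TRUE)) {
      fail("events", "contains times beyond the session duration")
    }
    caught <- ev$outcome == "caught"
    if (any(caught & is.na(ev$catch_time_s))) {
      fail("events$catch_time_s", "must be set for caught balls")
    }
    if (any(!caught & (!is.na(ev$catch_time_s) | !is.na(ev$return_time_s)))) {
      fail("events$catch_time_s", "must be unset for missed balls")
    }
    if (any(ev$catch_time_s < ev$spawn_time_s - 1e-9, na.rm = TRUE)) {
      fail("events$catch_time_s", "must be at or after the spawn time")
    }
    if (any(ev$return_time_s < ev$catch_time_s - 1e-9, na.rm = TRUE)) {
      fail("events$return_time_s", "must be at or after the catch time")
    }
    if (any(diff(ev$score_after) < 0)) {
      fail("events$score_after", "must be non-decreasing")
    }
    if (x$final_score != utils::tail(ev$score_after, 1)) {
      fail("final_score", "must equal the score after the last event")
    }
    if (x$final_score != sum(!is.na(ev$return_time_s))) {
      fail("final_score", "must equal the number of returned balls")
    }
  } else if (x$final_score != 0L) {
    fail("final_score", "must be 0 for a session with no events")
  }
  n_caught <- sum(ev$outcome == "caught")
  if (x$balls_caught != n_caught) fail("balls_caught", "does not match events")
  if (x$balls_missed != sum(ev$outcome == "missed")) {
    fail("balls_missed", "does not match events")
  }
  if (x$balls_spawned < n_caught + x$balls_missed) {
    fail("balls_spawned", "must be at least caught + missed")
  }
  if (x$final_score > n_caught) fail("final_score", "cannot exceed balls caught")
  invisible(x)
}

# ---------------------------------------------------------------------------
# session JSON

stage_to_list <- function(cfg) {
  out <- list(stage_id = cfg$stage_id, x0 = cfg$x0, incr_dist = cfg$incr_dist,
              dist_var = cfg$dist_var, speed0 = cfg$speed0,
              incr_speed = cfg$incr_speed, constant_speed = cfg$constant_speed,
              duration_s = cfg$duration_s, x_min = cfg$x_min, x_max = cfg$x_max)
  out[!vapply(out, is.null, logical(1))] # parameters a stage does not use
}

session_to_list <- function(x) {
  list(
    schema_version = x$schema_version,
    session_id = x$session_id,
    child_id = x$child_id,
    handedness = x$handedness,
    stage_config = stage_to_list(x$stage_config),
    events = x$events,
    final_score = x$final_score,
    balls_spawned = x$balls_spawned,
    balls_caught = x$balls_caught,
    balls_missed = x$balls_missed,
    clock_s = x$clock_s,
    hat_x = x$hat_x,
    home_x = x$home_x,
    rng_seed = x$rng_seed,
    started_at = x$started_at
  )
}

#' Write / read a session record as JSON
#'
#' `write_session()` serialises a `midcross_session` losslessly (full float
#' precision, embedded schema version); `read_session()` parses, migrates
#' older supported schema versions, validates every record invariant and
#' errors, naming the offending field, on violation. Unknown schema versions
#' are rejected.
#'
#' @param session A `midcross_session`.
#' @param path File path.
#' @return `write_session()` the path, invisibly; `read_session()` the
#'   validated `midcross_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "midcross_session"))
  validate_session(session)
  jsonlite::write_json(session_to_list(session), path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ver <- raw$schema_version
  if (is.null(ver)) stop("invalid session record: field 'schema_version' is missing",
                         call. = FALSE)
  if (identical(ver, "1.0")) {
    raw <- migrate_session_1_0(raw)
  } else if (!identical(ver, MIDCROSS_SCHEMA_VERSION)) {
    stop(sprintf("unsupported session schema version '%s' (reader supports %s; 1.0 via migration)",
                 ver, MIDCROSS_SCHEMA_VERSION), call. = FALSE)
  }
  cfgl <- raw$stage_config
  cfg <- stage_config(cfgl$stage_id, x0 = cfgl$x0, incr_dist = cfgl$incr_dist,
                      dist_var = cfgl$dist_var, speed0 = cfgl$speed0,
                      incr_speed = cfgl$incr_speed,
                      constant_speed = cfgl$constant_speed %||% 2,
                      duration_s = cfgl$duration_s,
                      x_min = cfgl$x_min, x_max = cfgl$x_max)
  ev <- raw$events
  if (is.null(ev) || length(ev) == 0L || NROW(ev) == 0L) {
    ev <- data.frame(index = integer(0), spawn_x = numeric(0),
                     spawn_time_s = numeric(0), fall_speed = numeric(0),
                     outcome = character(0), catch_time_s = numeric(0),
                     return_time_s = numeric(0), score_after = integer(0),
                     stringsAsFactors = FALSE)
  } else {
    for (col in c("catch_time_s", "return_time_s")) {
      if (is.null(ev[[col]])) ev[[col]] <- NA_real_
      ev[[col]] <- as.numeric(ev[[col]])
    }
    ev$index <- as.integer(ev$index)
    ev$score_after <- as.integer(ev$score_after)
    ev <- ev[, c("index", "spawn_x", "spawn_time_s", "fall_speed", "outcome",
                 "catch_time_s", "return_time_s", "score_after")]
  }
  record <- structure(
    list(schema_version = MIDCROSS_SCHEMA_VERSION,
         session_id = raw$session_id, child_id = raw$child_id,
         handedness = raw$handedness, stage_config = cfg, events = ev,
         final_score = as.integer(raw$final_score),
         balls_spawned = as.integer(raw$balls_spawned),
         balls_caught = as.integer(raw$balls_caught),
         balls_missed = as.integer(raw$balls_missed),
         clock_s = raw$clock_s, hat_x = raw$hat_x, home_x = raw$home_x,
         rng_seed = as.integer(raw$rng_seed),
         started_at = as.character(raw$started_at %||% NA_character_)),
    class = "midcross_session"
  )
  validate_session(record)
  record
}

# schema 1.0 stored a single per-session fall_speed; 1.1 stores it per event
migrate_session_1_0 <- function(raw) {
  if (is.null(raw$fall_speed)) {
    stop("invalid session record: field 'fall_speed' is missing (schema 1.0)",
         call. = FALSE)
  }
  if (NROW(raw$events) > 0L) raw$events$fall_speed <- raw$fall_speed
  raw$fall_speed <- NULL
  raw$schema_version <- MIDCROSS_SCHEMA_VERSION
  raw
}

# ---------------------------------------------------------------------------
# notes JSON

#' Write / read a notes record as JSON
#'
#' Round-trips a [notes_record()]. Notes with missing booleans are accepted
#' and flagged incomplete, not rejected.
#'
#' @param notes A `midcross_notes`.
#' @param path File path.
#' @export
write_notes <- function(notes, path) {
  stopifnot(inherits(notes, "midcross_notes"))
  jsonlite::write_json(unclass(notes)[setdiff(names(notes), "incomplete")],
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_notes
#' @export
read_notes <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ver <- raw$schema_version
  if (!identical(ver, MIDCROSS_SCHEMA_VERSION)) {
    stop(sprintf("unsupported notes schema version '%s'", ver %||% "<none>"),
         call. = FALSE)
  }
  as_na_flag <- function(v) if (is.null(v)) NA else as.logical(v)
  notes_record(
    session_id = raw$session_id,
    recorder_role = raw$recorder_role,
    followed_instructions = as_na_flag(raw$followed_instructions),
    maintained_visual_focus = as_na_flag(raw$maintained_visual_focus),
    gross_body_adjustments = as_na_flag(raw$gross_body_adjustments),
    verbal_cues_required = as_na_flag(raw$verbal_cues_required),
    distance_pattern_observed = as_na_flag(raw$distance_pattern_observed),
    free_text = raw$free_text %||% "",
    completed_at = as.character(raw$completed_at %||% NA_character_)
  )
}

# ---------------------------------------------------------------------------
# score-card JSON + CSV

#' Write / read a score card as JSON
#'
#' @param card A `midcross_card`.
#' @param path File path.
#' @export
write_card <- function(card, path) {
  stopifnot(inherits(card, "midcross_card"))
  out <- list(schema_version = MIDCROSS_SCHEMA_VERSION,
              session_id = card$session_id, stage_id = card$stage_id,
              criterion_points = card$criterion_points, total = card$total,
              classification = card$classification,
              provenance = card$provenance, incomplete = card$incomplete)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_card
#' @export
read_card <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(raw$schema_version, MIDCROSS_SCHEMA_VERSION)) {
    stop(sprintf("unsupported score-card schema version '%s'",
                 raw$schema_version %||% "<none>"), call. = FALSE)
  }
  card <- new_score_card(raw$criterion_points, stage_id = raw$stage_id,
                         provenance = raw$provenance,
                         session_id = raw$session_id,
                         incomplete = isTRUE(raw$incomplete))
  if (!identical(card$total, as.integer(raw$total)) ||
      !identical(card$classification, raw$classification)) {
    stop("invalid score card: field 'total'/'classification' inconsistent with criterion points",
         call. = FALSE)
  }
  card
}

#' Flat CSV export of score cards
#'
#' One row per session: identifiers, the eight criterion points, total,
#' classification, provenance (semicolon separated) and the incomplete flag.
#' `read_cards_csv()` reconstructs the same list of cards.
#'
#' @param cards A list of `midcross_card` objects.
#' @param path CSV file path.
#' @export
write_cards_csv <- function(cards, path) {
  stopifnot(length(cards) > 0, all(vapply(cards, inherits, logical(1),
                                          "midcross_card")))
  rows <- do.call(rbind, lapply(cards, function(card) {
    pts <- as.list(card$criterion_points)
    names(pts) <- paste0("criterion_", 1:8)
    data.frame(session_id = card$session_id, stage_id = card$stage_id,
               pts, total = card$total, classification = card$classification,
               provenance = paste(card$provenance, collapse = ";"),
               incomplete = card$incomplete, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cards_csv
#' @export
read_cards_csv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    new_score_card(unlist(r[paste0("criterion_", 1:8)]),
                   stage_id = r$stage_id,
                   provenance = strsplit(r$provenance, ";", fixed = TRUE)[[1]],
                   session_id = r$session_id, incomplete = r$incomplete)
  })
}

#' @export
print.midcross_notes <- function(x, ...) {
  cat(sprintf("<midcross notes> session %s, by %s%s\n", x$session_id,
              x$recorder_role, if (x$incomplete) " (incomplete)" else ""))
  cat(sprintf(
    "  instructions: %s | focus: %s | gross adjustments: %s | verbal cues: %s | miss pattern: %s\n",
    x$followed_instructions, x$maintained_visual_focus,
    x$gross_body_adjustments, x$verbal_cues_required,
    x$distance_pattern_observed))
  invisible(x)
}
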