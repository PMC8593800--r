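#' Per-session dashboard summary
#'
#' Computes the aggregates the therapist dashboard shows for a single
#' session: catch counts and rate, session tempo, the furthest contralateral
#' distance at which a ball was caught *and* returned (the child's
#' demonstrated crossing range), the miss-by-distance profile — equal-width
#' bins over the playfield, with attempts and misses per bin, the panel that
#' makes "missed more as distance increased" visible at a glance — and the
#' score-card total. Summaries are pure functions of their inputs.
#'
#' @param session A `midcross_session`.
#' @param card The matching `midcross_card` (same `session_id`).
#' @param n_bins Number of equal-width distance bins (default 6).
#' @return A `midcross_summary`: identifiers, counts, `catch_rate`
#'   (`NA` when no balls resolved), `mean_inter_ball_time_s`,
#'   `max_distance_reached`, `miss_by_distance` (bin_lo, bin_hi, attempts,
#'   misses), `score_card_total`, `date`, `empty` flag.
#' @export
summarize_session <- function(session, card, n_bins = 6) {
  stopifnot(inherits(session, "midcross_session"),
            inherits(card, "midcross_card"))
  if (!identical(session$session_id, card$session_id)) {
    stop("session and score card describe different sessions", call. = FALSE)
  }
  if (!is_scalar_number(n_bins) || n_bins < 1 || n_bins != round(n_bins)) {
    stop("`n_bins` must be a positive integer", call. = FALSE)
  }
  stats <- extract_stats(session)
  ev <- stats$events
  n_resolved <- stats$balls_caught + stats$balls_missed

  cfg <- session$stage_config
  breaks <- seq(cfg$x_min, cfg$x_max, length.out = n_bins + 1)
  bin <- if (nrow(ev)) {
    findInterval(ev$spawn_x, breaks, rightmost.closed = TRUE,
                 all.inside = TRUE)
  } else integer(0)
  attempts <- tabulate(bin, nbins = n_bins)
  misses <- tabulate(bin[ev$outcome == "missed"], nbins = n_bins)

  returned <- session$events$outcome == "caught" &
    !is.na(session$events$return_time_s)
  max_dist <- if (any(returned)) max(ev$challenge[returned]) else NA_real_

  structure(
    list(session_id = session$session_id, child_id = session$child_id,
         stage_id = cfg$stage_id,
         balls_caught = stats$balls_caught,
         balls_missed = stats$balls_missed,
         catch_rate = if (n_resolved > 0) stats$balls_caught / n_resolved
                      else NA_real_,
         mean_inter_ball_time_s = stats$mean_inter_ball_time_s,
         max_distance_reached = max_dist,
         miss_by_distance = data.frame(bin_lo = breaks[-(n_bins + 1)],
                                       bin_hi = breaks[-1],
                                       attempts = attempts, misses = misses),
         score_card_total = card$total,
         date = session$started_at,
         empty = n_resolved == 0L),
    class = "midcross_summary"
  )
}

#' Cross-session progress report for one child
#'
#' Orders a child's session summaries by date (falling back to the given
#' order when dates are missing) and fits, per stage, an ordinary
#' least-squares line of score-card total against session ordinal. The slope,
#' in points per session, is the dashboard's progress trend; it is defined
#' only when a stage has at least two sessions and is `NA` (flagged)
#' otherwise.
#'
#' @param summaries List of `midcross_summary` objects, all for one child.
#' @return A `midcross_progress`: `child_id`, `sessions` table (ordered
#'   date, stage_id, score_card_total, catch_rate) and `trend` table
#'   (stage_id, n_sessions, slope_points_per_session).
#' @export
build_progress <- function(summaries) {
  stopifnot(length(summaries) > 0,
            all(vapply(summaries, inherits, logical(1), "midcross_summary")))
  ids <- vapply(summaries, `[[`, character(1), "child_id")
  if (length(unique(ids)) != 1L) {
    stop("all summaries must describe the same child", call. = FALSE)
  }
  sess <- data.frame(
    session_id = vapply(summaries, `[[`, character(1), "session_id"),
    date = vapply(summaries, function(s) as.character(s$date), character(1)),
    stage_id = vapply(summaries, `[[`, integer(1), "stage_id"),
    score_card_total = vapply(summaries, `[[`, integer(1), "score_card_total"),
    catch_rate = vapply(summaries, `[[`, numeric(1), "catch_rate"),
    stringsAsFactors = FALSE
  )
  ord <- order(sess$date, na.last = FALSE)        # stable: ties keep input order
  sess <- sess[ord, , drop = FALSE]
  rownames(sess) <- NULL

  trend <- do.call(rbind, lapply(sort(unique(sess$stage_id)), function(sid) {
    tot <- sess$score_card_total[sess$stage_id == sid]
    slope <- if (length(tot) >= 2) {
      unname(stats::coef(stats::lm(tot ~ seq_along(tot)))[2])
    } else NA_real_
    data.frame(stage_id = sid, n_sessions = length(tot),
               slope_points_per_session = slope)
  }))

  structure(list(child_id = ids[1], sessions = sess, trend = trend),
            class = "midcross_progress")
}

#' Export dashboard tables
#'
#' `write_summaries_csv()` writes one tidy row per session (identifiers,
#' counts, catch rate, tempo, crossing range, score-card total);
#' `write_progress_json()` writes a progress report as JSON.
#'
#' @param summaries List of `midcross_summary`.
#' @param progress A `midcross_progress`.
#' @param path Output file path.
#' @export
write_summaries_csv <- function(summaries, path) {
  rows <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(session_id = s$session_id, child_id = s$child_id,
               stage_id = s$stage_id, date = as.character(s$date),
               balls_caught = s$balls_caught, balls_missed = s$balls_missed,
               catch_rate = s$catch_rate,
               mean_inter_ball_time_s = s$mean_inter_ball_time_s,
               max_distance_reached = s$max_distance_reached,
               score_card_total = s$score_card_total,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_summaries_csv
#' @export
write_progress_json <- function(progress, path) {
  stopifnot(inherits(progress, "midcross_progress"))
  jsonlite::write_json(unclass(progress), path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' Plot a miss-by-distance profile
#'
#' Convenience bar chart of the per-bin miss fraction from a session summary
#' (requires ggplot2). The characteristic midline-crossing signature is a
#' rising profile toward the contralateral edge.
#'
#' @param summary A `midcross_summary`.
#' @return A ggplot object.
#' @export
plot_miss_profile <- function(summary) {
  stopifnot(inherits(summary, "midcross_summary"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_miss_profile() needs the ggplot2 package", call. = FALSE)
  }
  df <- summary$miss_by_distance
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  df$miss_fraction <- ifelse(df$attempts > 0, df$misses / df$attempts, NA)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$miss_fraction)) +
    ggplot2::geom_col(width = (df$bin_hi - df$bin_lo)[1] * 0.9) +
    ggplot2::labs(x = "spawn position (game units)", y = "miss fraction",
                  title = sprintf("Session %s (stage %d)",
                                  summary$session_id, summary$stage_id))
}

#' @export
print.midcross_summary <- function(x, ...) {
  cat(sprintf("<midcross summary> session %s (child %s, stage %d)\n",
              x$session_id, x$child_id, x$stage_id))
  cat(sprintf("  caught %d / missed %d (rate %s), tempo %s s, range %s u, card %d/8\n",
              x$balls_caught, x$balls_missed,
              formatC(x$catch_rate, digits = 3, format = "fg"),
              formatC(x$mean_inter_ball_time_s, digits = 3, format = "fg"),
              formatC(x$max_distance_reached, digits = 3, format = "fg"),
              x$score_card_total))
  invisible(x)
}

#' @export
print.midcross_progress <- function(x, ...) {
  cat(sprintf("<midcross progress> child %s, %d session(s)\n",
              x$child_id, nrow(x$sessions)))
  print(x$trend, row.names = FALSE)
  invisible(x)
}
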