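# score card: gameplay criteria, pattern test, totals and classification

test_that("gameplay stats count outcomes and average the spawn gaps", {
  ev <- data.frame(spawn_x = c(1, 1.5, 2), challenge = c(1, 1.5, 2),
                   fall_speed = 2,
                   outcome = c("caught", "caught", "missed"),
                   stringsAsFactors = FALSE)
  st <- stats_from_vectors(ev$challenge, ev$outcome)
  expect_equal(st$balls_caught, 2)
  expect_equal(st$balls_missed, 1)

  # spawn times 0, 6, 13 -> gaps 6 and 7 -> mean 6.5
  s <- quick_session(1, seed = 1)
  s$events <- s$events[1:3, ]
  s$events$spawn_time_s <- c(0, 6, 13)
  s$events$catch_time_s <- s$events$spawn_time_s + 5
  s$events$return_time_s <- s$events$catch_time_s + 1
  s$events$score_after <- 1:3
  s$final_score <- 3L
  s$balls_spawned <- 3L; s$balls_caught <- 3L; s$balls_missed <- 0L
  expect_equal(extract_stats(s)$mean_inter_ball_time_s, 6.5)
})

test_that("engine round-trip: extracted stats match the session counters", {
  for (seed in 1:5) {
    s <- run_session(default_stage_config(4), "right",
                     make_profile("impaired", 0.5), seed = seed)
    st <- extract_stats(s)
    expect_equal(st$balls_caught, s$balls_caught)
    expect_equal(st$balls_missed, s$balls_missed)
    expect_equal(st$n_events, nrow(s$events))
  }
})

test_that("gameplay thresholds are strict: the boundary earns no point", {
  pts <- function(caught, missed, gap) {
    score_gameplay_criteria(midcross:::gameplay_stats(caught, missed, gap))
  }
  expect_equal(as.integer(pts(15, 3, 7.0)), c(1L, 1L, 1L))
  expect_equal(as.integer(pts(14, 4, 7.5)), c(0L, 0L, 0L)) # boundaries fail
  expect_equal(as.integer(pts(0, 16, 7.5)), c(0L, 0L, 0L))
  # undefined timing: criterion 3 scores 0 and is flagged
  p <- score_gameplay_criteria(midcross:::gameplay_stats(15, 0, NA_real_))
  expect_equal(as.integer(p), c(1L, 1L, 0L))
  expect_false(attr(p, "timing_defined"))
})

test_that("the pattern test is degenerate-safe and flags distance-linked misses", {
  all_caught <- stats_from_vectors(seq(1, 4, length.out = 16),
                                   rep("caught", 16))
  res <- detect_distance_pattern(all_caught, 999, seed = 1)
  expect_false(res$pattern)
  expect_equal(res$p_value, 1)

  # misses exactly at the 5 largest distances of 16: near-exhaustive
  # permutation null puts the observed correlation far in the tail
  ch <- seq(0.5, 8, length.out = 16)
  outcome <- ifelse(rank(ch) > 11, "missed", "caught")
  res <- detect_distance_pattern(stats_from_vectors(ch, outcome), 1e4,
                                 seed = 2)
  expect_true(res$pattern)
  expect_lte(res$p_value, 0.01)

  # constant challenge carries no distance information
  flat <- stats_from_vectors(rep(2, 10),
                             rep(c("caught", "missed"), 5))
  expect_false(detect_distance_pattern(flat, 99, seed = 1)$pattern)
})

test_that("coin-flip outcomes keep the pattern test near its nominal level", {
  # 1000 replicates: the binomial noise of a 200-replicate check (~1.5
  # points of error rate) would swamp the margin being asserted
  hits <- midcross:::with_seed(404, {
    vapply(1:1000, function(i) {
      ch <- stats::runif(16, 0.5, 7.5)
      outcome <- ifelse(stats::runif(16) < 0.5, "missed", "caught")
      detect_distance_pattern(stats_from_vectors(ch, outcome), 199,
                              seed = i)$pattern
    }, logical(1))
  })
  expect_lte(mean(hits), 0.07) # type-I error at nominal 0.05
})

test_that("null permutation p-values are close to uniform", {
  pvals <- midcross:::with_seed(505, {
    vapply(1:200, function(i) {
      ch <- stats::runif(16, 0.5, 7.5)
      outcome <- ifelse(stats::runif(16) < 0.4, "missed", "caught")
      st <- stats_from_vectors(ch, outcome)
      if (length(unique(outcome)) < 2) return(NA_real_)
      detect_distance_pattern(st, 199, seed = i)$p_value
    }, numeric(1))
  })
  pvals <- pvals[!is.na(pvals)]
  grid <- seq(0.05, 0.95, by = 0.05)
  ks <- max(abs(vapply(grid, function(q) mean(pvals <= q) - q, numeric(1))))
  expect_lt(ks, 1.63 / sqrt(length(pvals))) # KS bound at alpha = 0.01
})

test_that("the score card combines gameplay, pattern and observational points", {
  st <- midcross:::gameplay_stats(16, 0, 6.5, session_id = "sX")
  notes <- favourable_notes("sX")
  card <- score_card(st, notes)
  expect_equal(card$total, 8L)
  expect_equal(card$classification, "no_pathology_indicated")
  expect_false(card$incomplete)
  expect_equal(card$provenance,
               c(rep("gameplay", 3), rep("observation", 5)))

  # favourable criterion 4 + gameplay alone reaches exactly the threshold
  bad_obs <- notes_record("sX", "caretaker", FALSE, FALSE, TRUE, TRUE,
                          distance_pattern_observed = FALSE)
  card <- score_card(st, bad_obs)
  expect_equal(card$total, 4L)
  expect_equal(card$classification, "no_pathology_indicated")

  # weak gameplay + one favourable note stays below it
  weak <- midcross:::gameplay_stats(3, 12, 8.2, session_id = "sX")
  one_note <- notes_record("sX", "caretaker", TRUE, FALSE, TRUE, TRUE,
                           distance_pattern_observed = TRUE)
  card <- score_card(weak, one_note)
  expect_equal(card$total, 1L)
  expect_equal(card$classification, "further_assessment_needed")
})

test_that("missing notes zero the observational criteria and flag the card", {
  st <- midcross:::gameplay_stats(16, 0, 6.5, session_id = "sX")
  card <- score_card(st, notes = NULL)
  expect_equal(card$criterion_points[4:8], rep(0L, 5))
  expect_equal(card$total, 3L)
  expect_true(card$incomplete)
})

test_that("automated criterion 4 substitutes the permutation test with provenance", {
  s <- run_session(default_stage_config(1), "right",
                   make_profile("impaired", 1), seed = 3)
  st <- extract_stats(s)
  card <- score_card(st, favourable_notes(s$session_id),
                     use_automated_pattern = TRUE, seed = 11)
  expect_equal(card$provenance[4], "automated")
  expect_false(is.null(card$pattern_test))
  expect_equal(card$criterion_points[4],
               as.integer(!card$pattern_test$pattern))
})

test_that("classification flips exactly at 4 points over all 256 criterion vectors", {
  vectors <- expand.grid(rep(list(0:1), 8))
  for (i in seq_len(nrow(vectors))) {
    pts <- as.integer(vectors[i, ])
    card <- midcross:::new_score_card(pts)
    expect_equal(card$total, sum(pts))
    expect_equal(card$classification,
                 if (sum(pts) >= 4) "no_pathology_indicated"
                 else "further_assessment_needed")
  }
  expect_error(classify_total(9), "0..8")
})

test_that("simulated populations separate cleanly end to end", {
  cfg <- default_stage_config(1)
  clean <- vapply(1:200, function(s) {
    sess <- run_session(cfg, "right", make_profile("unimpaired"), seed = s)
    card <- score_card(extract_stats(sess), synthetic_notes(sess, "favorable"))
    card$classification == "no_pathology_indicated"
  }, logical(1))
  flagged <- vapply(1:200, function(s) {
    sess <- run_session(cfg, "right", make_profile("impaired", 1), seed = s)
    card <- score_card(extract_stats(sess),
                       synthetic_notes(sess, "unfavorable"))
    card$classification == "further_assessment_needed"
  }, logical(1))
  expect_gte(mean(clean), 0.95)
  expect_gte(mean(flagged), 0.95)
})
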