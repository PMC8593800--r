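# session engine: event loop, scoring mechanics, determinism, mirroring

test_that("a perfect player's session matches the closed-form cycle-time oracle", {
  # straight-line recomputation of the stage-1 timeline from the default
  # constants: fall = y_top/speed; the hat (speed 6, reaction 0.3) always
  # reaches the ball, so every ball is caught and the next spawns when the
  # hat is back within the return tolerance of the home edge.
  eng <- engine_params()
  cfg <- default_stage_config(1)
  grid <- function(x) ceiling(x / eng$dt - 1e-9) * eng$dt
  fall <- grid(eng$y_top / cfg$constant_speed)
  t <- 0; score <- 0
  exp_spawn_x <- exp_spawn_t <- exp_catch <- exp_return <- numeric(0)
  repeat {
    if (t >= cfg$duration_s - 1e-9) break
    x <- min(cfg$x0 + cfg$incr_dist * score, cfg$x_max)
    if (t + fall > cfg$duration_s) break
    ret <- t + fall + grid(((x + 7.5) - eng$return_tol) / 6)
    if (ret > cfg$duration_s) {
      exp_spawn_x <- c(exp_spawn_x, x); exp_spawn_t <- c(exp_spawn_t, t)
      exp_catch <- c(exp_catch, t + fall); exp_return <- c(exp_return, NA)
      break
    }
    exp_spawn_x <- c(exp_spawn_x, x); exp_spawn_t <- c(exp_spawn_t, t)
    exp_catch <- c(exp_catch, t + fall); exp_return <- c(exp_return, ret)
    score <- score + 1; t <- ret
  }

  s <- run_session(cfg, "right", perfect_player(), seed = 42)
  expect_equal(s$events$spawn_x, exp_spawn_x)
  expect_equal(s$events$spawn_time_s, exp_spawn_t)
  expect_equal(s$events$catch_time_s, exp_catch)
  expect_equal(s$events$return_time_s, exp_return)
  expect_equal(s$final_score, sum(!is.na(exp_return)))
  expect_true(all(s$events$outcome == "caught"))
})

test_that("scripted-outcome sessions reproduce the stage recurrences exactly", {
  # for each stage, replay the session's own outcome sequence through a
  # 20-line recomputation of the spawn/speed recurrences and compare
  for (sid in 1:4) {
    cfg <- default_stage_config(sid)
    s <- run_session(cfg, "right", make_profile("impaired", 0.8), seed = 31)
    ev <- s$events
    score <- 0
    for (k in seq_len(nrow(ev))) {
      if (sid == 1) {
        expect_equal(ev$spawn_x[k],
                     min(cfg$x0 + cfg$incr_dist * score, cfg$x_max))
      } else if (sid == 3) {
        expect_equal(ev$spawn_x[k], cfg$x0)
        expect_equal(ev$fall_speed[k], cfg$speed0 + cfg$incr_speed * score)
      }
      if (sid != 3) expect_equal(ev$fall_speed[k], cfg$constant_speed)
      expect_equal(ev$score_after[k],
                   score + as.integer(!is.na(ev$return_time_s[k])))
      score <- ev$score_after[k]
    }
    expect_equal(s$final_score, score)
  }
})

test_that("a player that never moves scores zero and the stage-1 ball never advances", {
  s <- run_session(default_stage_config(1), "right", frozen_player(),
                   seed = 3)
  expect_equal(s$final_score, 0L)
  expect_true(all(s$events$outcome == "missed"))
  expect_equal(unique(s$events$spawn_x), 1.0) # X0 forever: score never moved
})

test_that("after a missed ball stages 1 and 3 respawn at the same position", {
  for (sid in c(1, 3)) {
    s <- run_session(default_stage_config(sid), "right",
                     make_profile("impaired", 1), seed = 8)
    ev <- s$events
    miss_then_next <- which(ev$outcome == "missed")
    miss_then_next <- miss_then_next[miss_then_next < nrow(ev)]
    expect_true(length(miss_then_next) > 0)
    expect_equal(ev$spawn_x[miss_then_next + 1], ev$spawn_x[miss_then_next])
  }
})

test_that("identical inputs give byte-identical session records", {
  a <- run_session(default_stage_config(2), "left",
                   make_profile("impaired", 0.5), seed = 17)
  b <- run_session(default_stage_config(2), "left",
                   make_profile("impaired", 0.5), seed = 17)
  expect_identical(a, b)
})

test_that("score trajectory is non-decreasing and equals the returned-ball count", {
  midcross:::with_seed(21, {
    for (i in 1:25) {
      s <- run_session(random_stage_config(), "right", random_player(),
                       seed = i)
      expect_true(all(diff(s$events$score_after) >= 0))
      expect_equal(s$final_score, sum(!is.na(s$events$return_time_s)))
      expect_true(all(s$events$spawn_x >= -7.5 & s$events$spawn_x <= 7.5))
      expect_lte(s$balls_caught + s$balls_missed, s$balls_spawned)
    }
  })
})

test_that("stage-1 spawn positions are non-decreasing for any player", {
  midcross:::with_seed(22, {
    for (i in 1:10) {
      s <- run_session(default_stage_config(1), "right", random_player(),
                       seed = i)
      expect_true(all(diff(s$events$spawn_x) >= 0))
    }
  })
})

test_that("stage-3 fall speed tracks the score before each ball; other stages stay constant", {
  s3 <- run_session(default_stage_config(3), "right", perfect_player(),
                    seed = 5)
  score_before <- c(0, utils::head(s3$events$score_after, -1))
  expect_equal(s3$events$fall_speed, 2 + 0.1 * score_before)
  for (sid in c(1, 2, 4)) {
    s <- run_session(default_stage_config(sid), "right", perfect_player(),
                     seed = 5)
    expect_equal(unique(s$events$fall_speed), 2)
  }
})

test_that("left-handed play is the event-for-event mirror of right-handed play", {
  for (sid in 1:4) {
    right_cfg <- default_stage_config(sid)
    left_cfg <- if (is.null(right_cfg$x0)) right_cfg else {
      cfg <- right_cfg; cfg$x0 <- -cfg$x0; cfg
    }
    p <- make_profile("impaired", 0.6)
    r <- run_session(right_cfg, "right", p, seed = 13)
    l <- run_session(left_cfg, "left", p, seed = 13)
    expect_equal(l$events$spawn_x, -r$events$spawn_x)
    l$events$spawn_x <- NULL
    r$events$spawn_x <- NULL
    expect_equal(l$events, r$events)
    expect_equal(l$final_score, r$final_score)
    expect_equal(l$home_x, -r$home_x)
  }
})

test_that("sessions run the full two-minute clock with no event beyond it", {
  for (sid in 1:4) {
    s <- quick_session(sid, seed = 2)
    expect_equal(s$clock_s, 120)
    expect_true(all(s$events$spawn_time_s <= 120))
    expect_true(all(s$events$return_time_s <= 120, na.rm = TRUE))
  }
})
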