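test_that("bout integration matches a literal Euler loop and the ODE solution", {
  gt <- gt_elite()
  v <- simulate_bout(gt, effort = 1, v_start = 0, v_target = 8, rate = 10)

  # literal forward-Euler oracle
  ve <- 0
  oracle <- 0
  while (ve < 8) {
    ve <- ve + TRUE_A0 / 10 * (1 - ve / TRUE_V0)
    oracle <- c(oracle, ve)
  }
  expect_equal(v, oracle, tolerance = 1e-10)

  # continuous-time closed form V0 (1 - exp(-A0 t / V0)), Euler error O(1/rate)
  tt <- (seq_along(v) - 1) / 10
  expect_lt(max(abs(v - TRUE_V0 * (1 - exp(-TRUE_A0 * tt / TRUE_V0)))),
            TRUE_A0 / 10)
})

test_that("maximal-effort samples touch the envelope exactly before noise", {
  gt <- gt_elite()
  for (vs in c(0, 1.3, 2.9)) {
    v <- simulate_bout(gt, effort = 1, v_start = vs, v_target = 8.5, rate = 10)
    a <- diff(v) * 10
    expect_equal(a, TRUE_A0 * (1 - v[-length(v)] / TRUE_V0), tolerance = 1e-9)
  }
  # least squares on one generated segment recovers the envelope parameters
  v <- simulate_bout(gt, effort = 1, v_start = 3, v_target = 8.6, rate = 10)
  fit <- lm(I(diff(v) * 10) ~ v[-length(v)])
  expect_equal(coef(fit)[[1]], TRUE_A0, tolerance = 1e-6)
  expect_equal(coef(fit)[[2]], TRUE_SLOPE, tolerance = 1e-6)
})

test_that("bout preconditions are enforced", {
  gt <- gt_elite()
  expect_error(simulate_bout(gt, v_start = 0, v_target = 9.5), "exceeds")
  expect_error(simulate_bout(gt, v_start = 5, v_target = 4), "v_start")
  expect_error(simulate_bout(gt, effort = 0, v_start = 0, v_target = 5),
               "effort")
})

test_that("session traces have the scheduled length and are reproducible", {
  gt <- gt_elite()
  cfg <- season_config()
  tr1 <- simulate_session(gt, "game", duration_s = 5400, config = cfg, seed = 9)
  expect_identical(length(tr1$v), 54000L)  # 90 min at 10 Hz
  tr2 <- simulate_session(gt, "game", duration_s = 5400, config = cfg, seed = 9)
  expect_identical(tr1$v, tr2$v)
  tr3 <- simulate_session(gt, "game", duration_s = 5400, config = cfg, seed = 10)
  expect_false(identical(tr1$v, tr3$v))
  expect_error(simulate_session(gt, "game", duration_s = 60, config = cfg),
               "too short")
})

test_that("noise-free per-bin maxima sit on the envelope within the Euler bound", {
  gt <- gt_elite()
  tr <- simulate_session(gt, "game", config = probe_config(0), seed = 3)
  a <- compute_acceleration(tr$v, tr$rate)
  binned <- bin_max_acceleration(tr$v[-length(tr$v)], a)  # unfiltered
  keep <- binned$bin_center > 3 & binned$a_max > 0
  env <- TRUE_A0 * (1 - binned$bin_center[keep] / TRUE_V0)
  euler_bound <- TRUE_A0^2 / (10 * TRUE_V0) + TRUE_A0 * 0.05 / TRUE_V0
  expect_lt(max(abs(binned$a_max[keep] - env)), euler_bound)
})

test_that("session summaries are exact on degenerate traces and conserve distance", {
  tr <- session_trace(rep(2, 1000), kind = "training")  # 2 m/s for 100 s
  s <- summarise_session(tr)
  expect_equal(s[["total_distance_m"]], 200)
  expect_equal(s[["accel_count_2"]], 0)
  expect_equal(s[["decel_count_2"]], 0)
  expect_equal(s[["max_speed_mps"]], 2)

  z <- summarise_session(session_trace(rep(0, 500), kind = "training"))
  expect_equal(z[["total_distance_m"]], 0)
  expect_equal(z[["max_speed_mps"]], 0)
  expect_equal(z[["sprint_count"]], 0)

  tr2 <- simulate_session(gt_elite(), "game", config = season_config(),
                          seed = 14)
  s2 <- summarise_session(tr2)
  zones <- sum(s2[paste0("dist_zone", 1:5, "_m")])
  expect_equal(zones, s2[["total_distance_m"]], tolerance = 1e-6)
})

test_that("peak filtered acceleration matches the envelope at its own velocity", {
  gt <- gt_elite()
  tr <- simulate_session(gt, "game", config = probe_config(0), seed = 21)
  af <- lowpass_filter(compute_acceleration(tr$v, tr$rate), tr$rate)
  i <- which.max(af)
  v_at_peak <- tr$v[i]  # start-of-step velocity of the peak sample
  expect_equal(max(af), TRUE_A0 * (1 - v_at_peak / TRUE_V0),
               tolerance = 0.05 * TRUE_A0)
})

test_that("season schedule has the configured shape and games follow trainings", {
  cfg <- season_config(n_players = 2, n_games = 4, n_trainings = 10,
                       game_duration_s = 480, training_duration_s = 420,
                       n_bouts_game = 12, n_bouts_training = 10)
  s <- simulate_season(cfg, seed = 5)
  expect_identical(nrow(s$summaries), 28L)  # 2 players x 14 sessions
  expect_identical(sum(s$schedule$kind == "game"), 4L)
  expect_identical(sum(s$schedule$kind == "training"), 10L)
  for (gd in s$schedule$date[s$schedule$kind == "game"])
    expect_true(any(s$schedule$date[s$schedule$kind == "training"] < gd))
})

test_that("zero drift keeps every week's truth identical; seeds reproduce seasons", {
  cfg <- season_config(n_players = 2, n_games = 2, n_trainings = 4,
                       game_duration_s = 480, training_duration_s = 420,
                       n_bouts_game = 12, n_bouts_training = 10,
                       drift_sd = 0)
  s <- simulate_season(cfg, seed = 8)
  for (p in unique(s$truth$player_id)) {
    tw <- s$truth[s$truth$player_id == p, ]
    expect_equal(length(unique(tw$A0_true)), 1L)
    expect_equal(length(unique(tw$V0_true)), 1L)
  }
  s2 <- simulate_season(cfg, seed = 8)
  expect_identical(s$profiles, s2$profiles)
  expect_identical(s$summaries, s2$summaries)
  # games-only generation reproduces the game traces byte-for-byte
  s3 <- simulate_season(cfg, seed = 8, sessions = "games")
  expect_identical(s$profiles, s3$profiles)
})

test_that("trace CSV round-trips", {
  tr <- simulate_session(gt_elite(), "training", duration_s = 300,
                         config = season_config(n_bouts_training = 6),
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  tr2 <- read_trace_csv(path, kind = "training")
  expect_equal(tr2$v, tr$v, tolerance = 1e-6)
  expect_equal(tr2$rate, tr$rate)
})
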