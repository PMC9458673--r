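test_that("mape matches its definition", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(2, 1), 0.5)
  set.seed(60)
  yt <- runif(100, 0.5, 5) * sample(c(-1, 1), 100, TRUE)
  yp <- yt + rnorm(100)
  acc <- 0
  for (i in 1:100) acc <- acc + abs(yt[i] - yp[i]) / abs(yt[i])
  expect_equal(mape(yt, yp), acc / 100, tolerance = 1e-12)
  expect_error(mape(c(1, 0, 2), c(1, 1, 1)), "rows: 2")
  expect_error(mape(1:3, 1:2), "lengths")
})

test_that("target re-scaling is the stated affine map on the training range", {
  r <- rescale_targets(c(-0.6, -0.5, -0.4), c(4, 4.5, 5))
  expect_equal(r$slope_rescaled, c(4, 4.5, 5))

  same <- rescale_targets(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$slope_rescaled, c(1, 2, 3))
  expect_equal(same$a, 0)
  expect_equal(same$b, 1)

  set.seed(61)
  sl <- rnorm(40, -0.5, 0.1)
  ic <- rnorm(40, 4.7, 0.4)
  tr <- 1:30
  rr <- rescale_targets(sl, ic, train = tr)
  expect_equal(min(rr$slope_rescaled[tr]), min(ic[tr]), tolerance = 1e-12)
  expect_equal(max(rr$slope_rescaled[tr]), max(ic[tr]), tolerance = 1e-12)
  expect_error(rescale_targets(rep(1, 5), 1:5), "degenerate")
})

test_that("paired bootstrap is calibrated for self-comparison and separates a doubled error", {
  set.seed(62)
  rows <- data.frame(player_id = rep(sprintf("p%d", 1:10), each = 6),
                     game_id = rep(1:6, 10),
                     y_true = rep(4.7, 60))
  rows$y_pred <- rows$y_true + rnorm(60, 0, 0.3)

  self <- paired_bootstrap_compare(rows, rows, B = 500, seed = 1)
  expect_equal(self$mean_diff, 0)
  expect_gte(self$p, 0.9)

  worse <- rows
  worse$y_pred <- rows$y_true + 2 * (rows$y_pred - rows$y_true)
  cmp <- paired_bootstrap_compare(rows, worse, B = 1000, seed = 2)
  expect_lt(cmp$ci[2], 0)            # CI excludes zero, a is better
  expect_lt(cmp$p, 0.05)
  expect_true(cmp$ci[1] <= cmp$mean_diff && cmp$mean_diff <= cmp$ci[2])

  cmp2 <- paired_bootstrap_compare(rows, worse, B = 1000, seed = 2)
  expect_identical(cmp, cmp2)        # seeded determinism

  few <- rows[rows$player_id %in% c("p1", "p2"), ]
  expect_error(paired_bootstrap_compare(few, few), "5 shared players")
})

test_that("control task beats chance and is deterministic", {
  s <- eval_season()
  ctl <- run_control_task(s, min_games = 8)
  expect_named(ctl$mape, c("intercept", "slope"))
  expect_lt(ctl$mape[["intercept"]], 0.05)  # near-identifiable by design

  # permutation baseline: shuffling targets across games destroys the signal
  s_perm <- s
  set.seed(63)
  perm <- sample(nrow(s_perm$profiles))
  s_perm$profiles$intercept <- s_perm$profiles$intercept[perm]
  s_perm$profiles$slope <- s_perm$profiles$slope[perm]
  ctl_perm <- run_control_task(s_perm, min_games = 8)
  expect_gt(ctl_perm$mape[["intercept"]], 1.3 * ctl$mape[["intercept"]])
  # ... and is comparable to the predict-the-training-mean ceiling
  pr <- s$profiles[s$profiles$valid, ]
  meanbase <- mape(pr$intercept, rep(mean(pr$intercept), nrow(pr)))
  expect_gt(ctl_perm$mape[["intercept"]], 0.5 * meanbase)

  expect_identical(ctl$rows, run_control_task(s, min_games = 8)$rows)
})

test_that("experiment scores every task on identical keys and conserves its summaries", {
  s <- eval_season()
  ex <- run_experiment(s, min_games = 10, B = 200, seed = 4)

  # same test keys for every task
  for (tk in unique(ex$rows$task)) {
    sub <- ex$rows[ex$rows$task == tk & ex$rows$target == "slope", ]
    expect_identical(sort(paste(sub$player_id, sub$game_id)), ex$test_keys)
  }

  # ranking MAPEs recomputable from the row-level predictions
  for (i in seq_len(nrow(ex$ranking))) {
    sub <- ex$rows[ex$rows$task == ex$ranking$task[i] &
                     ex$rows$target == ex$ranking$target[i], ]
    ape <- abs(sub$y_true - sub$y_pred) / abs(sub$y_true)
    expect_equal(ex$ranking$mape[i], mean(tapply(ape, sub$player_id, mean)),
                 tolerance = 1e-12)
  }

  # forecasting reference appears in every contrast and p values are valid
  expect_true(all(ex$contrasts$p > 0 & ex$contrasts$p <= 1))
  expect_true(all(ex$contrasts$ci_lo <= ex$contrasts$mean_diff &
                    ex$contrasts$mean_diff <= ex$contrasts$ci_hi))

  # reruns with the same seed are identical
  ex2 <- run_experiment(s, min_games = 10, B = 200, seed = 4)
  expect_identical(ex$ranking, ex2$ranking)
  expect_identical(ex$contrasts, ex2$contrasts)
})

test_that("per-player scope fits individual models and still shares keys", {
  s <- eval_season()
  exI <- run_experiment(s, scope = "I", min_games = 12, B = 200, seed = 5)
  expect_true(all(exI$ranking$scope %in% "I"))
  for (tk in unique(exI$rows$task)) {
    sub <- exI$rows[exI$rows$task == tk & exI$rows$target == "intercept", ]
    expect_identical(sort(paste(sub$player_id, sub$game_id)), exI$test_keys)
  }
})
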