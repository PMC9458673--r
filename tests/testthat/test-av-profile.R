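test_that("acceleration is the backward difference in physical units", {
  expect_equal(compute_acceleration(c(3.0, 3.1, 3.3), rate = 10), c(1, 2))
  expect_equal(compute_acceleration(rep(2.5, 50), rate = 10), rep(0, 49))

  set.seed(1)
  v <- runif(500, 0, 9)
  a <- compute_acceleration(v, rate = 10)
  oracle <- numeric(length(v) - 1)
  for (i in 2:length(v)) oracle[i - 1] <- (v[i] - v[i - 1]) * 10
  expect_identical(a, oracle)

  t_bad <- c(0, 0.1, 0.2, 0.35, 0.4)
  expect_error(compute_acceleration(runif(5), rate = 10, t = t_bad),
               "index 4")
  expect_error(compute_acceleration(3), "two velocity samples")
})

test_that("filter has unit DC gain and the first-order analytic gains at cutoff", {
  expect_equal(lowpass_filter(rep(3, 200), 10, filter_spec(mode = "causal"))[100:200],
               rep(3, 101), tolerance = 1e-6)
  expect_equal(lowpass_filter(rep(3, 200), 10), rep(3, 200), tolerance = 1e-6)

  # long 1 Hz sinusoid at 10 Hz sampling; measure steady-state amplitude
  # and lag by projecting on the quadrature pair
  n <- 5000
  tt <- (0:(n - 1)) / 10
  x <- sin(2 * pi * 1 * tt)
  gain_and_lag <- function(y) {
    core <- 500:(n - 500)
    cs <- cos(2 * pi * tt[core])
    sn <- sin(2 * pi * tt[core])
    b <- coef(lm(y[core] ~ sn + cs - 1))
    list(gain = sqrt(sum(b^2)), lag = atan2(-b[["cs"]], b[["sn"]]))
  }
  cz <- gain_and_lag(lowpass_filter(x, 10, filter_spec(mode = "causal")))
  expect_equal(cz$gain, 1 / sqrt(2), tolerance = 0.02)
  zp <- gain_and_lag(lowpass_filter(x, 10, filter_spec(mode = "zero-phase")))
  expect_equal(zp$gain, 1 / 2, tolerance = 0.02)
  expect_lt(abs(zp$lag), 0.01)  # radians; zero phase

  expect_error(lowpass_filter(x, 10, filter_spec(cutoff_hz = 6)), "Nyquist")
})

test_that("filter attenuation is monotone in frequency", {
  n <- 4000
  tt <- (0:(n - 1)) / 10
  gains <- vapply(c(0.2, 0.5, 1, 2, 3, 4), function(f) {
    y <- lowpass_filter(sin(2 * pi * f * tt), 10)
    core <- 500:(n - 500)
    max(abs(y[core]))
  }, 0)
  expect_true(all(diff(gains) < 0))
})

test_that("zero-phase filter agrees with signal::filtfilt away from the edges", {
  set.seed(4)
  x <- rnorm(2000)
  mine <- lowpass_filter(x, 10)
  bf <- signal::butter(1, 1 / 5)
  ref <- signal::filtfilt(bf, x)
  core <- 100:1900
  expect_equal(mine[core], ref[core], tolerance = 1e-6)
  # causal mode matches signal::filter exactly (same initial conditions)
  expect_equal(lowpass_filter(x, 10, filter_spec(mode = "causal")),
               as.numeric(signal::filter(bf, x)), tolerance = 1e-10)
})

test_that("bin maxima match hand examples and a brute-force oracle", {
  b <- bin_max_acceleration(c(3.04, 3.06, 3.17), c(1.2, 1.5, 0.9))
  expect_equal(b$bin_center, c(3.05, 3.15))
  expect_equal(b$a_max, c(1.5, 0.9))
  expect_equal(b$n, c(2L, 1L))

  b1 <- bin_max_acceleration(5.23, 2.2)
  expect_equal(b1$bin_center, 5.25)
  expect_equal(b1$a_max, 2.2)

  set.seed(7)
  v <- runif(10000, 0, 9.5)
  a <- rnorm(10000)
  got <- bin_max_acceleration(v, a)
  oracle <- new.env()
  for (i in seq_along(v)) {
    key <- as.character(floor(v[i] / 0.1))
    prev <- oracle[[key]]
    if (is.null(prev) || a[i] > prev) oracle[[key]] <- a[i]
  }
  keys <- sort(as.integer(ls(oracle)))
  expect_equal(got$bin_center, (keys + 0.5) * 0.1)
  expect_equal(got$a_max,
               vapply(as.character(keys), function(k) oracle[[k]], 0,
                      USE.NAMES = FALSE))
  expect_error(bin_max_acceleration(numeric(), numeric()), "empty")
})

test_that("envelope fit is exact on a line and matches the normal equations", {
  centers <- seq(3.05, 8.95, by = 0.1)
  exact <- data.frame(bin_center = centers, a_max = 4.7 - 0.53 * centers)
  fit <- fit_profile(exact)
  expect_equal(fit$slope, -0.53, tolerance = 1e-10)
  expect_equal(fit$intercept, 4.7, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- data.frame(bin_center = centers, a_max = rep(1.8, length(centers)))
  ffit <- fit_profile(flat)
  expect_equal(ffit$slope, 0, tolerance = 1e-12)
  expect_equal(ffit$intercept, 1.8, tolerance = 1e-12)

  set.seed(11)
  rb <- data.frame(bin_center = seq(3.05, 7.95, by = 0.1),
                   a_max = runif(50, 0.5, 4))
  rfit <- fit_profile(rb)
  # 2x2 normal equations oracle
  x <- rb$bin_center; y <- rb$a_max
  sol <- solve(matrix(c(length(x), sum(x), sum(x), sum(x^2)), 2),
               c(sum(y), sum(x * y)))
  expect_equal(rfit$intercept, sol[1], tolerance = 1e-10)
  expect_equal(rfit$slope, sol[2], tolerance = 1e-10)

  few <- fit_profile(exact[1:5, ])
  expect_false(few$valid)
  expect_true(is.na(few$slope))
})

test_that("profile extraction recovers known envelopes from clean sessions", {
  gt <- gt_elite()
  for (sd_ in 1:6) {
    tr <- simulate_session(gt, "game", config = probe_config(0), seed = sd_)
    fit <- av_profile(tr)
    expect_true(fit$valid)
    expect_lt(abs(fit$intercept - TRUE_A0) / TRUE_A0, 0.05)
    expect_lt(abs(fit$slope - TRUE_SLOPE) / abs(TRUE_SLOPE), 0.05)
    expect_gt(fit$r_squared, 0.99)
  }
})

test_that("profiles scale with the envelope (linearity in the ground truth)", {
  for (sc in c(0.8, 1.2)) {
    gt <- ground_truth_profile("x", A0 = TRUE_A0 * sc, V0 = TRUE_V0)
    tr <- simulate_session(gt, "game", config = probe_config(0), seed = 2)
    fit <- av_profile(tr)
    expect_lt(abs(fit$intercept - sc * TRUE_A0) / (sc * TRUE_A0), 0.05)
    expect_lt(abs(fit$slope + sc * TRUE_A0 / TRUE_V0) /
                (sc * TRUE_A0 / TRUE_V0), 0.05)
  }
})

test_that("slow traces yield an invalid profile, not a fit", {
  tr <- session_trace(rep(2, 2000) + sin(1:2000 / 50), kind = "training")
  fit <- av_profile(tr)
  expect_false(fit$valid)
  expect_true(is.na(fit$slope))
  expect_error(predict(fit), "invalid")
})

test_that("av_profile methods are coherent", {
  tr <- simulate_session(gt_elite(), "game", config = probe_config(0), seed = 1)
  fit <- av_profile(tr)
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(unname(predict(fit, 4)), fit$intercept + 4 * fit$slope)
  expect_equal(length(residuals(fit)), fit$n_bins_used)
  expect_output(print(fit), "intercept")
  v_sim <- simulate(fit)
  expect_true(is.numeric(v_sim) && length(v_sim) > 10)
  expect_lt(max(v_sim), -fit$intercept / fit$slope + 1e-6)
})
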