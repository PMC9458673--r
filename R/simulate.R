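#' Ground-truth athlete envelope
#'
#' Describes a simulated athlete's true maximal-effort capacity: maximal
#' theoretical acceleration `A0` (m/s^2, the true profile intercept),
#' maximal velocity `V0` (m/s), and the weekly fractional random-walk
#' standard deviation `drift_sd` applied to both. The true envelope is
#' `a_max(v) = A0 * (1 - v / V0)`, so the true slope is `-A0 / V0` (1/s).
#'
#' @param athlete_id Identifier.
#' @param A0 Maximal acceleration at zero velocity, m/s^2 (> 0).
#' @param V0 Maximal velocity, m/s (> 0).
#' @param drift_sd Weekly multiplicative random-walk sd (fractional, >= 0).
#' @return Object of class `"ground_truth_profile"` with derived fields
#'   `intercept_true` and `slope_true`.
#' @examples
#' ground_truth_profile("p1", A0 = 4.72, V0 = 8.86)
#' @export
ground_truth_profile <- function(athlete_id, A0 = 4.72, V0 = 8.86,
                                 drift_sd = 0) {
  if (!is.numeric(A0) || A0 <= 0) stop("'A0' must be positive")
  if (!is.numeric(V0) || V0 <= 0) stop("'V0' must be positive")
  if (drift_sd < 0) stop("'drift_sd' must be non-negative")
  structure(list(athlete_id = athlete_id, A0 = A0, V0 = V0,
                 drift_sd = drift_sd,
                 intercept_true = A0, slope_true = -A0 / V0),
            class = "ground_truth_profile")
}

#' @export
print.ground_truth_profile <- function(x, ...) {
  cat(sprintf("Ground truth %s: A0 %.3f m/s^2, V0 %.3f m/s (slope %.4f 1/s), drift sd %.3g/wk\n",
              x$athlete_id, x$A0, x$V0, x$slope_true, x$drift_sd))
  invisible(x)
}

#' Sample a roster of ground-truth athlete profiles
#'
#' Athlete capacities are drawn around the elite-footballer means:
#' `A0 ~ N(4.72, 0.35)` m/s^2 and `V0 ~ N(8.86, 0.45)` m/s (truncated to
#' stay positive and physiological).
#'
#' @param n Number of athletes.
#' @param A0_mean,A0_sd,V0_mean,V0_sd Population parameters.
#' @param drift_sd Weekly drift sd given to every athlete.
#' @return List of [ground_truth_profile()] objects.
#' @export
player_population <- function(n, A0_mean = 4.72, A0_sd = 0.35,
                              V0_mean = 8.86, V0_sd = 0.45,
                              drift_sd = 0.01) {
  A0 <- pmax(2, rnorm(n, A0_mean, A0_sd))
  V0 <- pmax(6, rnorm(n, V0_mean, V0_sd))
  lapply(seq_len(n), function(i)
    ground_truth_profile(sprintf("p%02d", i), A0[i], V0[i], drift_sd))
}

#' Season simulation settings
#'
#' Defaults emulate a 1.5-season professional football data set: 42
#' rostered players, 196 training sessions and 74 games scheduled at 4
#' team sessions per week, sampled at 10 Hz with additive Gaussian
#' velocity noise of sd 0.1 m/s, and squads of 14 (games) / 20
#' (trainings) drawn per session. Default durations are per-player
#' active recording times (60 min for games - few players log a full 90
#' minutes of locomotion - and 45 min of active drills for trainings).
#'
#' @param n_players Roster size.
#' @param n_games,n_trainings Team session counts for the whole period.
#' @param sessions_per_week Team sessions per scheduled week.
#' @param noise_sd Additive velocity noise sd, m/s.
#' @param seed Default seed used by [simulate_season()] when none is given.
#' @param bout_mix Named proportions of `maximal` vs `submaximal` bouts
#'   within a session; must sum to 1.
#' @param game_duration_s,training_duration_s Session durations, s.
#' @param rate Sampling rate, Hz.
#' @param game_squad,training_squad Players drawn per session (capped at
#'   `n_players`).
#' @param n_bouts_game,n_bouts_training Locomotor bouts per session.
#' @param game_effort,training_effort Ranges `(lo, hi)` of the per-session
#'   effort multiplier drawn uniformly for each session: maximal bouts
#'   express the envelope `E * A0 * (1 - v / V0)`, emulating game-to-game
#'   variation in how much of the athlete's capacity the match demands.
#' @param decel_rate Constant deceleration of ramp-downs, m/s^2.
#' @param drift_sd Weekly fractional random-walk sd of athlete capacities.
#' @return Object of class `"season_config"`.
#' @examples
#' season_config(n_players = 2, n_games = 4, n_trainings = 10)
#' @export
season_config <- function(n_players = 42, n_games = 74, n_trainings = 196,
                          sessions_per_week = 4, noise_sd = 0.1, seed = 1,
                          bout_mix = c(maximal = 0.6, submaximal = 0.4),
                          game_duration_s = 3600, training_duration_s = 2700,
                          rate = 10, game_squad = 14, training_squad = 20,
                          n_bouts_game = 55, n_bouts_training = 32,
                          game_effort = c(0.88, 1), training_effort = c(0.8, 1),
                          decel_rate = 3, drift_sd = 0.01) {
  if (any(c(n_players, n_games, n_trainings, sessions_per_week) < 1))
    stop("counts must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (!all(c("maximal", "submaximal") %in% names(bout_mix)) ||
      abs(sum(bout_mix) - 1) > 1e-8)
    stop("'bout_mix' needs proportions 'maximal' and 'submaximal' summing to 1")
  if (game_duration_s <= 0 || training_duration_s <= 0)
    stop("durations must be positive")
  for (ef in list(game_effort, training_effort))
    if (length(ef) != 2 || any(ef <= 0) || any(ef > 1) || ef[1] > ef[2])
      stop("effort ranges must be (lo, hi) within (0, 1]")
  structure(list(n_players = n_players, n_games = n_games,
                 n_trainings = n_trainings,
                 sessions_per_week = sessions_per_week, noise_sd = noise_sd,
                 seed = seed, bout_mix = bout_mix,
                 game_duration_s = game_duration_s,
                 training_duration_s = training_duration_s, rate = rate,
                 game_squad = min(game_squad, n_players),
                 training_squad = min(training_squad, n_players),
                 n_bouts_game = n_bouts_game,
                 n_bouts_training = n_bouts_training,
                 game_effort = game_effort,
                 training_effort = training_effort,
                 decel_rate = decel_rate, drift_sd = drift_sd),
            class = "season_config")
}

## Run code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate one constant-effort acceleration bout
#'
#' Forward-Euler integration of `dv/dt = effort * A0 * (1 - v / V0)` at
#' step `1/rate`, from `v_start` until the velocity reaches `v_target`
#' (or `max_duration_s` elapses). At `effort = 1` every step satisfies
#' `diff(v) * rate = A0 * (1 - v_i / V0)` exactly at the step's starting
#' velocity, i.e. the samples touch the true envelope before any noise or
#' filtering.
#'
#' @param profile A [ground_truth_profile()].
#' @param effort Fraction of maximal effort in (0, 1].
#' @param v_start,v_target Start / target velocity, m/s
#'   (`0 <= v_start < v_target <= V0`).
#' @param rate Sampling rate, Hz.
#' @param max_duration_s Safety cap on bout duration.
#' @return Velocity samples including the starting sample.
#' @examples
#' v <- simulate_bout(ground_truth_profile("p"), 1, 0, 8, rate = 10)
#' @export
simulate_bout <- function(profile, effort = 1, v_start = 0, v_target = NULL,
                          rate = 10, max_duration_s = 60) {
  stopifnot(inherits(profile, "ground_truth_profile"))
  if (is.null(v_target)) v_target <- 0.95 * profile$V0
  if (v_target > profile$V0)
    stop(sprintf("v_target (%.2f) exceeds the athlete's V0 (%.2f m/s)",
                 v_target, profile$V0))
  if (effort <= 0 || effort > 1) stop("'effort' must be in (0, 1]")
  if (v_start < 0 || v_start >= v_target)
    stop("need 0 <= v_start < v_target")
  V0 <- profile$V0
  k <- effort * profile$A0 / (rate * V0)  # per-step fractional gap closure
  n <- if (v_target < V0)
    ceiling(log((V0 - v_target) / (V0 - v_start)) / log1p(-k))
  else Inf
  n <- min(n, max_duration_s * rate)
  ## closed form of the Euler recursion v[i+1] = v[i] + k * (V0 - v[i])
  c(v_start, V0 - (V0 - v_start) * (1 - k)^seq_len(n))
}

## deceleration ramp from v0 (exclusive) down to vt at constant rate
decel_ramp <- function(v0, vt, decel_rate, rate) {
  if (vt >= v0) return(numeric(0))
  s <- seq(v0, vt, by = -decel_rate / rate)
  s <- s[-1]
  if (!length(s) || s[length(s)] > vt) s <- c(s, vt)
  s
}

#' Simulate a full session velocity trace
#'
#' Concatenates walking, submaximal bouts, maximal-effort accelerations
#' and constant-rate deceleration ramps into a continuous velocity signal
#' of exactly `duration_s * rate` samples, then adds i.i.d. Gaussian
#' velocity noise (sd `config$noise_sd`) clipped at zero. Maximal efforts
#' start below the envelope-fit range and their target velocities span
#' moderate speeds up to near `V0`, so every velocity bin used by
#' [av_profile()] is visited by envelope-touching samples.
#'
#' @param profile A [ground_truth_profile()] (current, possibly drifted,
#'   capacities).
#' @param kind `"game"` or `"training"` (selects duration default and bout
#'   counts from `config`).
#' @param duration_s Session duration in seconds; defaults to the
#'   config's duration for `kind`.
#' @param config A [season_config()].
#' @param seed Optional seed for a reproducible trace.
#' @param player_id,session_id,date Metadata stored on the trace.
#' @return A [session_trace()].
#' @export
simulate_session <- function(profile, kind = c("training", "game"),
                             duration_s = NULL, config = season_config(),
                             seed = NULL, player_id = profile$athlete_id,
                             session_id = NA_character_, date = NA) {
  kind <- match.arg(kind)
  if (is.null(duration_s))
    duration_s <- if (kind == "game") config$game_duration_s else
      config$training_duration_s
  with_seed(seed, {
    sv <- simulate_session_velocity(profile, kind, duration_s, config)
    v <- sv$v
    if (config$noise_sd > 0)
      v <- pmax(0, v + rnorm(length(v), 0, config$noise_sd))
    tr <- session_trace(v, rate = config$rate, player_id = player_id,
                        session_id = session_id, date = date, kind = kind)
    tr$effort <- sv$effort
    tr
  })
}

## noise-free velocity construction; consumes RNG for bout layout
simulate_session_velocity <- function(profile, kind, duration_s, config) {
  rate <- config$rate
  V0 <- profile$V0
  n_target <- round(duration_s * rate)
  n_bouts <- if (kind == "game") config$n_bouts_game else config$n_bouts_training
  ## per-session effort expression: the fraction of capacity the session
  ## actually demands of the athlete's maximal efforts
  erange <- if (kind == "game") config$game_effort else config$training_effort
  E <- runif(1, erange[1], erange[2])
  n_max <- max(2L, round(n_bouts * config$bout_mix[["maximal"]]))
  n_sub <- max(0L, n_bouts - n_max)
  n_long <- max(1L, round(0.25 * n_max))
  n_short <- n_max - n_long
  ## maximal efforts: low starts (below the fit range), targets spanning
  ## moderate speed to near V0
  st <- runif(n_max, 0.2, min(2.8, 0.32 * V0))
  tg <- c(runif(n_short, 0.48, 0.85), runif(n_long, 0.90, 0.985)) * V0
  is_max <- rep(c(TRUE, FALSE), c(n_max, n_sub))
  ord <- sample(n_max + n_sub)
  segs <- vector("list", 8L * (n_max + n_sub) + 2L)
  si <- 1L
  add <- function(s) { segs[[si]] <<- s; si <<- si + 1L }
  add(runif(1, 0.3, 0.8) + numeric(round(runif(1, 5, 15) * rate)))
  cur <- segs[[1L]][1L]
  cruise_at <- integer(0)  # indices of padding-eligible cruise segments
  for (j in ord) {
    if (is_max[j]) {
      s0 <- st[j]; t0 <- tg[j]   # maximal bouts are the first n_max indices
    } else {
      s0 <- cur
      t0 <- runif(1, 0.17, 0.45) * V0
    }
    if (is_max[j]) {
      if (s0 > cur + 1e-9) {
        seg <- simulate_bout(profile, effort = runif(1, 0.3, 0.6),
                             v_start = cur, v_target = s0, rate = rate)
        add(seg[-1]); cur <- seg[length(seg)]
      } else if (s0 < cur) {
        seg <- decel_ramp(cur, s0, config$decel_rate, rate)
        if (length(seg)) { add(seg); cur <- seg[length(seg)] }
      }
      seg <- simulate_bout(profile, effort = E, v_start = cur,
                           v_target = max(t0, cur + 0.5), rate = rate)
      add(seg[-1]); cur <- seg[length(seg)]
    } else if (t0 > cur + 0.2) {
      seg <- simulate_bout(profile, effort = runif(1, 0.3, 0.6),
                           v_start = cur, v_target = t0, rate = rate)
      add(seg[-1]); cur <- seg[length(seg)]
    }
    add(cur + numeric(round(rate)))  # 1 s hold
    cr <- runif(1, 0.5, 2.5)
    seg <- decel_ramp(cur, cr, config$decel_rate, rate)
    if (length(seg)) { add(seg); cur <- seg[length(seg)] }
    add(cur + numeric(round(runif(1, 8, 15) * rate)))
    cruise_at <- c(cruise_at, si - 1L)
  }
  segs <- segs[seq_len(si - 1L)]
  n_have <- sum(lengths(segs))
  deficit <- n_target - n_have
  if (deficit < 0)
    stop(sprintf("duration %.0f s too short for %d bouts (need >= %.0f s)",
                 duration_s, n_bouts, n_have / rate))
  if (deficit > 0) {
    ## stretch recovery cruises to fill the scheduled duration
    w <- runif(length(cruise_at))
    extra <- floor(deficit * w / sum(w))
    extra[1L] <- extra[1L] + deficit - sum(extra)
    for (q in seq_along(cruise_at)) {
      k <- cruise_at[q]
      segs[[k]] <- c(segs[[k]], segs[[k]][1L] + numeric(extra[q]))
    }
  }
  v <- unlist(segs, use.names = FALSE)
  list(v = v[seq_len(n_target)], effort = E)
}

#' Summarise a session trace into commercial-style features
#'
#' Computes the per-session scalar features a tracking vendor typically
#' reports: total distance, distance per speed zone, de-bounced
#' acceleration/deceleration episode counts on the filtered acceleration
#' signal, maximal speed, mean moving speed, sprint count, peak filtered
#' acceleration and duration. One episode is counted per contiguous
#' supra-threshold stretch.
#'
#' @param trace A [session_trace()].
#' @param filter A [filter_spec()] for the acceleration signal.
#' @param zones Speed-zone edges in m/s (default 2, 4, 5.5, 7; zones are
#'   `[0,2), [2,4), [4,5.5), [5.5,7), >=7`).
#' @param accel_thresholds Acceleration episode thresholds, m/s^2.
#' @param sprint_speed Sprint threshold, m/s.
#' @param moving_speed Minimum speed considered "moving", m/s.
#' @return Named numeric vector of 15 features.
#' @examples
#' tr <- session_trace(rep(2, 1000), kind = "training")
#' summarise_session(tr)[["total_distance_m"]]  # 200 m
#' @export
summarise_session <- function(trace, filter = filter_spec(),
                              zones = c(2, 4, 5.5, 7),
                              accel_thresholds = c(2, 3),
                              sprint_speed = 7, moving_speed = 0.5) {
  stopifnot(inherits(trace, "session_trace"))
  v <- trace$v
  rate <- trace$rate
  af <- if (length(v) > 12)
    lowpass_filter(compute_acceleration(v, rate), rate, filter)
  else numeric(0)
  summarise_from(v, af, rate, zones, accel_thresholds, sprint_speed,
                 moving_speed)
}

## summary computation on a precomputed filtered-acceleration signal,
## shared with the season loop
summarise_from <- function(v, af, rate, zones = c(2, 4, 5.5, 7),
                           accel_thresholds = c(2, 3), sprint_speed = 7,
                           moving_speed = 0.5) {
  episodes <- function(x, th) {
    if (!length(x)) return(0L)
    sum(diff(c(FALSE, x > th)) == 1L)
  }
  d <- v / rate
  zi <- findInterval(v, zones)
  zone_d <- vapply(0:length(zones), function(z) sum(d[zi == z]), 0)
  out <- c(total_distance_m = sum(d),
           setNames(zone_d, paste0("dist_zone", seq_along(zone_d), "_m")),
           setNames(vapply(accel_thresholds, function(th) episodes(af, th), 0),
                    paste0("accel_count_", accel_thresholds)),
           setNames(vapply(accel_thresholds, function(th) episodes(-af, th), 0),
                    paste0("decel_count_", accel_thresholds)),
           max_speed_mps = max(v),
           mean_moving_speed_mps =
             if (any(v > moving_speed)) mean(v[v > moving_speed]) else 0,
           sprint_count = episodes(v, sprint_speed),
           peak_accel_mps2 = if (length(af)) max(af) else 0,
           duration_s = length(v) / rate)
  out
}
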