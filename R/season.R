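#' Simulate a season of sessions with known ground truth
#'
#' Builds a weekly schedule interleaving trainings and games, applies a
#' multiplicative weekly random walk (sd `drift_sd`) independently to each
#' athlete's `A0` and `V0`, draws per-session squads, and generates every
#' participant's velocity trace. Traces are processed streamingly: each is
#' summarised ([summarise_session()]), optionally reduced to raw-signal
#' features ([extract_features()]), and - for games - profiled
#' ([av_profile()]); the trace itself is discarded unless `keep_traces`.
#'
#' Each trace is generated from a seed derived deterministically from
#' `seed` and the (session, player) indices, so the same configuration and
#' seed reproduce the identical data set, and generating only the games
#' (`sessions = "games"`) yields byte-identical game traces.
#'
#' @param config A [season_config()].
#' @param profiles Optional list of [ground_truth_profile()]s (defaults to
#'   [player_population()] of size `config$n_players`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param features Also extract the raw-signal feature catalogue per trace.
#' @param keep_traces Retain every [session_trace()] (memory-hungry).
#' @param sessions `"all"` or `"games"` (skip training traces; their
#'   schedule rows are kept).
#' @param min_bins Passed to [av_profile()] for game profiling.
#' @return Object of class `"av_season"`: list with `schedule`,
#'   `roster`, `truth` (per player-week true capacities), `profiles`
#'   (per player-game fitted coefficients with the session-realized truth
#'   - capacity times the session's effort expression - attached),
#'   `summaries`, `features` (or `NULL`), `config`, `seed`, and
#'   optionally `traces`.
#' @examples
#' cfg <- season_config(n_players = 2, n_games = 2, n_trainings = 4,
#'                      game_duration_s = 480, training_duration_s = 480,
#'                      n_bouts_game = 12, n_bouts_training = 10)
#' s <- simulate_season(cfg, seed = 1)
#' head(s$profiles)
#' @export
simulate_season <- function(config = season_config(), profiles = NULL,
                            seed = config$seed, features = FALSE,
                            keep_traces = FALSE,
                            sessions = c("all", "games"), min_bins = 10) {
  sessions <- match.arg(sessions)
  stopifnot(inherits(config, "season_config"))
  setup <- with_seed(seed, season_setup(config, profiles))
  sched <- setup$schedule
  roster <- setup$roster
  truth <- setup$truth
  part <- setup$participation

  run <- part
  if (sessions == "games")
    run <- part[part$kind == "game", , drop = FALSE]
  n_run <- nrow(run)
  summaries <- vector("list", n_run)
  feats <- if (features) vector("list", n_run) else NULL
  prof_rows <- vector("list", n_run)
  traces <- if (keep_traces) vector("list", n_run) else NULL

  for (r in seq_len(n_run)) {
    row <- run[r, ]
    gt <- ground_truth_profile(row$player_id, A0 = row$A0_true,
                               V0 = row$V0_true,
                               drift_sd = config$drift_sd)
    tr_seed <- trace_seed(seed, row$session_idx, row$player_idx)
    tr <- simulate_session(gt, kind = row$kind, config = config,
                           seed = tr_seed, player_id = row$player_id,
                           session_id = row$session_id, date = row$date)
    af <- lowpass_filter(compute_acceleration(tr$v, config$rate),
                         config$rate)
    summaries[[r]] <- summarise_from(tr$v, af, config$rate)
    if (features) feats[[r]] <- extract_features(tr)
    if (row$kind == "game") {
      p <- profile_from(tr$v, af, min_bins = min_bins)
      prof_rows[[r]] <- data.frame(
        player_id = row$player_id, session_id = row$session_id,
        date = row$date, slope = p$slope, intercept = p$intercept,
        r_squared = p$r_squared, n_bins = p$n_bins_used, valid = p$valid,
        effort = tr$effort,
        A0_capacity = row$A0_true, V0_capacity = row$V0_true,
        intercept_true = tr$effort * row$A0_true,
        slope_true = -tr$effort * row$A0_true / row$V0_true,
        stringsAsFactors = FALSE)
    }
    if (keep_traces) traces[[r]] <- tr
  }

  smat <- do.call(rbind, summaries)
  summaries <- data.frame(player_id = run$player_id,
                          session_id = run$session_id, date = run$date,
                          kind = run$kind, smat, stringsAsFactors = FALSE)
  if (features) {
    fmat <- do.call(rbind, feats)
    feats <- data.frame(player_id = run$player_id,
                        session_id = run$session_id, date = run$date,
                        kind = run$kind, fmat, stringsAsFactors = FALSE)
  }
  profs <- do.call(rbind, prof_rows[!vapply(prof_rows, is.null, TRUE)])
  rownames(profs) <- NULL

  structure(list(schedule = sched, roster = roster, truth = truth,
                 participation = part, profiles = profs,
                 summaries = summaries, features = feats,
                 config = config, seed = seed, traces = traces),
            class = "av_season")
}

#' @export
print.av_season <- function(x, ...) {
  ng <- sum(x$schedule$kind == "game")
  nt <- sum(x$schedule$kind == "training")
  cat(sprintf("Synthetic season: %d players, %d games + %d trainings over %d weeks (seed %d)\n",
              nrow(x$roster), ng, nt, max(x$schedule$week), x$seed))
  cat(sprintf("  %d player-sessions, %d game profiles (%d valid)\n",
              nrow(x$summaries), nrow(x$profiles), sum(x$profiles$valid)))
  invisible(x)
}

## deterministic per-trace seed below 2^31
trace_seed <- function(seed, session_idx, player_idx) {
  as.integer((as.numeric(seed) * 104729 + session_idx * 7919 +
                player_idx * 104417) %% 2147483647)
}

## schedule + roster + drift + participation; assumes caller seeded the RNG
season_setup <- function(config, profiles = NULL) {
  if (is.null(profiles))
    profiles <- player_population(config$n_players,
                                  drift_sd = config$drift_sd)
  if (!length(profiles)) stop("need at least one player")
  n_p <- length(profiles)
  roster <- data.frame(
    player_idx = seq_len(n_p),
    player_id = vapply(profiles, `[[`, "", "athlete_id"),
    A0 = vapply(profiles, `[[`, 0, "A0"),
    V0 = vapply(profiles, `[[`, 0, "V0"),
    drift_sd = vapply(profiles, `[[`, 0, "drift_sd"),
    stringsAsFactors = FALSE)

  ## weekly schedule: games spread evenly, trainings fill the remainder,
  ## trainings precede games within a week
  n_total <- config$n_games + config$n_trainings
  n_weeks <- ceiling(n_total / config$sessions_per_week)
  game_week <- pmin(n_weeks, floor((seq_len(config$n_games) - 0.5) /
                                     config$n_games * n_weeks) + 1L)
  slots_left <- tabulate(game_week, n_weeks)
  tr_per_week <- config$sessions_per_week - slots_left
  ## allocate exactly n_trainings among weeks, never negative
  tr_per_week <- pmax(0L, tr_per_week)
  excess <- sum(tr_per_week) - config$n_trainings
  w <- n_weeks
  while (excess > 0) {                # trim from the final weeks
    cut <- min(excess, tr_per_week[w])
    tr_per_week[w] <- tr_per_week[w] - cut
    excess <- excess - cut
    w <- w - 1L
  }
  while (excess < 0) {                # add extra trainings early on
    w <- if (w >= n_weeks || w < 1L) 1L else w
    tr_per_week[w] <- tr_per_week[w] + 1L
    excess <- excess + 1L
    w <- w + 1L
  }
  origin <- as.Date("2019-08-05")     # a Monday
  rows <- list(); k <- 0L; g <- 0L
  for (wk in seq_len(n_weeks)) {
    n_tr <- tr_per_week[wk]
    n_gm <- sum(game_week == wk)
    n_s <- n_tr + n_gm
    if (!n_s) next
    days <- round(seq(1, 6, length.out = max(n_s, 2L)))[seq_len(n_s)]
    days <- days + cumsum(c(0, diff(days) == 0))  # force distinct days
    for (j in seq_len(n_s)) {
      k <- k + 1L
      kind <- if (j <= n_tr) "training" else "game"
      if (kind == "game") g <- g + 1L
      rows[[k]] <- data.frame(
        session_idx = k,
        session_id = sprintf("s%03d", k),
        date = origin + (wk - 1L) * 7L + days[j] - 1L,
        week = wk, kind = kind, stringsAsFactors = FALSE)
    }
  }
  sched <- do.call(rbind, rows)

  ## weekly multiplicative random walk on A0 and V0, per player
  drift_mult <- function(sd_) {
    m <- matrix(1, n_p, n_weeks)
    if (sd_ > 0 && n_weeks > 1)
      m[, -1] <- exp(t(apply(matrix(rnorm(n_p * (n_weeks - 1), 0, sd_),
                                    n_p), 1, cumsum)))
    m
  }
  mA <- drift_mult(config$drift_sd)
  mV <- drift_mult(config$drift_sd)
  truth <- data.frame(
    player_idx = rep(seq_len(n_p), n_weeks),
    player_id = rep(roster$player_id, n_weeks),
    week = rep(seq_len(n_weeks), each = n_p),
    A0_true = as.vector(mA) * rep(roster$A0, n_weeks),
    V0_true = as.vector(mV) * rep(roster$V0, n_weeks),
    stringsAsFactors = FALSE)
  truth$intercept_true <- truth$A0_true
  truth$slope_true <- -truth$A0_true / truth$V0_true

  ## squad draws: a core of regulars plus occasional players
  wts <- rep(c(1, 0.25), c(ceiling(0.6 * n_p), n_p - ceiling(0.6 * n_p)))
  part <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    size <- if (sched$kind[i] == "game") config$game_squad else
      config$training_squad
    ids <- sort(sample.int(n_p, size, prob = wts))
    tw <- truth[truth$week == sched$week[i], ]
    part[[i]] <- data.frame(
      session_idx = sched$session_idx[i], session_id = sched$session_id[i],
      date = sched$date[i], week = sched$week[i], kind = sched$kind[i],
      player_idx = ids, player_id = roster$player_id[ids],
      A0_true = tw$A0_true[ids], V0_true = tw$V0_true[ids],
      stringsAsFactors = FALSE)
  }
  list(schedule = sched, roster = roster, truth = truth,
       participation = do.call(rbind, part))
}
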