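# Shared fixtures; everything is generated in code at test time.

TRUE_A0 <- 4.72
TRUE_V0 <- 8.86
TRUE_SLOPE <- -TRUE_A0 / TRUE_V0

gt_elite <- function(drift_sd = 0) {
  ground_truth_profile("p1", A0 = TRUE_A0, V0 = TRUE_V0, drift_sd = drift_sd)
}

# full-effort, short-session config for extraction checks
probe_config <- function(noise_sd = 0, duration = 1200) {
  season_config(noise_sd = noise_sd, game_effort = c(1, 1),
                game_duration_s = duration, n_bouts_game = 40)
}

# small season usable by pooling / evaluation tests; built lazily once
.fixture_env <- new.env()
eval_season <- function() {
  if (is.null(.fixture_env$season)) {
    cfg <- season_config(n_players = 6, n_games = 18, n_trainings = 36,
                         game_duration_s = 1500, training_duration_s = 900,
                         n_bouts_game = 30, n_bouts_training = 14,
                         game_squad = 5, training_squad = 6)
    .fixture_env$season <- simulate_season(cfg, seed = 42, features = TRUE)
  }
  .fixture_env$season
}
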