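# avprofiler

Acceleration-velocity profiling and performance prediction from GNSS
velocity traces.

## The problem

Wearable 10 Hz GNSS receivers give team-sport practitioners a per-session
velocity signal for every player. A compact summary of a player's maximal
locomotor capacity is the in-situ **acceleration-velocity (A-V) profile**:
during maximal efforts, the highest acceleration a player produces falls
approximately linearly with running velocity,

    a_max(v) = Y_b + Y_a * v,     Y_a < 0,

so the intercept `Y_b` (m/s²) estimates the theoretical maximal
acceleration, the slope `Y_a` (1/s) its decline per unit velocity, and
`-Y_b / Y_a` the maximal running velocity. The applied question for
practitioners: **can the features a tracking vendor reports for past
training sessions and games predict the profile a player will express in
the next game?**

`avprofiler` implements the full analysis chain:

* **Profile extraction** (`av_profile()`): backward-difference
  acceleration `a_i = (v_i - v_{i-1})·ω`, first-order Butterworth
  low-pass at 1 Hz (zero-phase by default), maximal acceleration per
  0.1 m/s velocity bin, and an OLS envelope fit over velocities above
  3 m/s. Returns a classed object with `print`, `summary`, `coef`,
  `predict`, `residuals`, `plot` and `simulate` methods.
* **Predictor pooling** (`mean_pool()`, `exponential_pool()`,
  `build_design_matrix()`): the last `L = 5` sessions before each game
  aggregated by arithmetic mean or softmax exponential-decay weights
  `w_j = exp(-β t_j) / Σ_k exp(-β t_k)` over days-before-game `t`.
* **Signal features** (`extract_features()`, `select_top_k()`): a
  27-feature time/frequency-domain catalogue computed directly from the
  velocity signal, with univariate F-test top-k selection and a
  Dickey-Fuller stationarity check (`dickey_fuller_stat()`).
* **Models** (`fit_ridge()`, `forecast_series()`): ridge regression with
  chronological cross-validation, and uni-modal forecasting baselines
  (naive, drift, classic Theta, FourTheta, FFT harmonic regression) with
  ensemble averaging.
* **Evaluation** (`run_experiment()`, `mape()`,
  `paired_bootstrap_compare()`): every task scored by mean absolute
  percentage error on the same chronological 80/20 per-player holdout,
  with paired bootstrap contrasts against the forecasting reference.
* **Synthetic seasons** (`simulate_season()`): because club tracking data
  are proprietary, a generator produces seasons of 10 Hz traces from
  known ground-truth envelopes (default: 42 players, 196 trainings + 74
  games over 1.5 seasons), with weekly capacity drift, per-session effort
  expression, and additive velocity noise — so every estimate the package
  produces can be validated against recoverable truth.

## Worked example

```r
library(avprofiler)

athlete <- ground_truth_profile("p07", A0 = 4.72, V0 = 8.86)
game <- simulate_session(athlete, kind = "game",
                         config = season_config(), seed = 42)
fit <- av_profile(game)
fit
#> Acceleration-velocity profile
#>   p07 / NA (NA)
#>   intercept 4.836 m/s^2, slope -0.5135 1/s  (v0 9.42 m/s)
#>   r^2 0.9898 over 59 bins above 3 m/s
```

The fitted intercept (4.836 m/s²) and slope (-0.513 1/s) recover the
athlete's true envelope (A0 = 4.72, slope = -0.533) to within a few
percent from a single noisy 60-minute game; `plot(fit)` shows the binned
maxima with the fitted envelope.

A miniature season and the full task comparison:

```r
cfg <- season_config(n_players = 4, n_games = 12, n_trainings = 24,
                     game_duration_s = 1500, training_duration_s = 900,
                     n_bouts_game = 30, n_bouts_training = 14,
                     game_squad = 4, training_squad = 4)
season <- simulate_season(cfg, seed = 7, features = TRUE)
ex <- run_experiment(season, min_games = 10, B = 500, seed = 1)
ex
#> Prediction-task comparison (scope G, split 0.80, 12 test games)
#> Mean MAPE by task (per-player aggregation):
#>                   task    target scope aggregation   mape
#>                control intercept     G        none 0.0282
#>   ridge_exp_commercial intercept     G exponential 0.0451
#>  ridge_mean_commercial intercept     G        mean 0.0477
#>      forecast_ensemble intercept     I        none 0.0574
#>       ridge_exp_signal intercept     G exponential 0.0651
#>      ridge_mean_signal intercept     G        mean 0.0654
#>                control     slope     G        none 0.0398
#>   ridge_exp_commercial     slope     G exponential 0.0570
#>  ridge_mean_commercial     slope     G        mean 0.0575
#>      forecast_ensemble     slope     I        none 0.0707
#>      ridge_mean_signal     slope     G        mean 0.0751
#>       ridge_exp_signal     slope     G exponential 0.0933
```

Each row is a prediction task's mean MAPE (a fraction: 0.0282 means
2.8%). The *control* task — predicting a game's coefficients from that
same game's summary features — bounds what is predictable at all;
past-window tasks (pooled ridge, forecasting) are consistently worse,
and the choice between mean and exponential pooling barely matters.
`ex$contrasts` holds paired bootstrap comparisons against the
forecasting reference, and `plot(ex)` the per-game error distributions.

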