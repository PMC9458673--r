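---
title: "Methods: acceleration-velocity profiling and its prediction tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acceleration-velocity profiling and its prediction tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avprofiler)
```

## The model

During a maximal running effort, the acceleration an athlete can produce
declines approximately linearly with current velocity:

$$a_{\max}(v) \;=\; A_0\,\Big(1 - \frac{v}{V_0}\Big),$$

where $A_0$ (m/s²) is the theoretical maximal acceleration at zero
velocity and $V_0$ (m/s) the maximal running velocity. A game's
**A-V profile** is the fitted pair (intercept $Y_b \approx A_0$, slope
$Y_a \approx -A_0/V_0$) of this envelope, estimated from the session's
10 Hz velocity signal. The package's central assumption — shared by all
in-situ profiling methods — is that over a long enough session the
athlete produces *some* maximal or near-maximal effort in every velocity
band above the fit threshold, so that per-bin maxima trace the envelope.

## Profile extraction, step by step

1. **Differencing.** `compute_acceleration()` forms
   $a_i = (v_i - v_{i-1})\,\omega$ with $\omega$ the sampling rate.
   Taken literally, a velocity difference per sample is in m/s per
   0.1 s; the scaling by $\omega$ makes the result a physical
   acceleration, which is the only reading compatible with intercepts
   near 4.7 m/s².
2. **Filtering.** `lowpass_filter()` applies a first-order Butterworth
   low-pass at 1 Hz. The default is a forward-backward (zero-phase)
   pass: it squares the magnitude response (gain $1/2$ at the cut-off
   instead of $1/\sqrt2$) and cancels the phase lag, so filtered
   acceleration stays aligned with velocity — the property that matters
   when samples are assigned to velocity bins. A causal single-pass mode
   is available. Coefficients come from `signal::butter()`; the filter
   itself runs through `stats::filter()`'s C recursion with
   point-symmetric mirror padding at both ends, which keeps a full
   season's 200M samples tractable. Unit tests verify the analytic DC
   and cut-off gains and agreement with `signal::filtfilt()` away from
   the edges.
3. **Velocity/acceleration alignment.** Acceleration sample $i$ (the
   step from $v_{i-1}$ to $v_i$) is paired with the *start-of-step*
   velocity $v_{i-1}$. For an effort riding the envelope,
   $\Delta v\,\omega = A_0(1 - v_{i-1}/V_0)$ holds exactly at sample
   resolution, so this pairing is unbiased. Pairing with the end-of-step
   velocity instead inflates both coefficients by the factor
   $1 + A_0/(\omega V_0)$ — about 5% at 10 Hz for elite sprint
   parameters, a bias visible in bin residuals and large relative to the
   accuracy the package aims for. Midpoint pairing halves but does not
   remove it.
4. **Binning.** `bin_max_acceleration()` keeps the maximal filtered
   acceleration per left-closed 0.1 m/s velocity bin (bin centers
   represent bins in the fit). Maxima, not quantiles: the envelope is a
   maximum by definition, and the filter has already suppressed
   single-sample noise spikes.
5. **Envelope fit.** `fit_profile()` runs OLS on bins with center
   strictly above 3 m/s (below that, technique and rest periods dominate
   rather than capacity). Two guards:
   * at least `min_bins = 10` retained bins, otherwise the profile is
     flagged invalid rather than fitted;
   * only bins whose maximum is positive (`a_min = 0`) enter the fit. A
     bin whose best sample is a deceleration or cruise was never visited
     *while accelerating*; it carries no envelope information, and a
     single such bin (e.g. a $-3$ m/s² ramp sample) can drag the OLS fit
     arbitrarily. This is a method parameter, configurable.

## The synthetic season generator

Real club tracking data are proprietary, so the package validates its
pipeline on synthetic seasons with recoverable ground truth
(`simulate_season()`). The generator emulates, per player-session:

* **Intermittent locomotion** as a continuous velocity trace: walking
  and cruising segments, submaximal build-ups, maximal-effort
  accelerations integrated by forward Euler on
  $\dot v = E\,A_0(1 - v/V_0)$ at the output rate (so the envelope
  identity is exact at sample resolution), and constant $-3$ m/s²
  deceleration ramps. Maximal efforts start below the 3 m/s fit
  threshold — their filter step-transients then fall outside the fitted
  range — and their target velocities span moderate speeds up to
  $0.985\,V_0$, so every bin the fit uses is crossed by
  envelope-touching samples.
* **Effort expression** $E$: one uniform draw per session
  (games 0.88-1.00, trainings 0.80-1.00) multiplying the envelope in
  maximal bouts. Games differ in what they demand of a player (opponent,
  role, score state); the realized profile of a given game is
  $E\,A_0(1-v/V_0)$, and the stored per-game truth includes $E$. This is
  what makes same-day summary features genuinely more informative about
  a game's profile than any pooled history — the property the control
  task probes.
* **Week-scale drift**: an independent multiplicative random walk
  (sd 0.01/week) on each athlete's $A_0$ and $V_0$, giving the slow
  evolution of capacities over a 1.5-season horizon. Together with
  between-player spreads of $A_0 \sim N(4.72, 0.35)$ and
  $V_0 \sim N(8.86, 0.45)$, the season-level dispersion of fitted
  coefficients lands near values reported for elite football cohorts.
* **Measurement noise**: additive i.i.d. Gaussian velocity noise
  (sd 0.1 m/s), clipped at zero. This is a deliberately harsh proxy for
  GNSS Doppler speed noise, which in reality is smaller and
  autocorrelated; differencing amplifies it strongly at high frequency,
  which is exactly what the 1 Hz low-pass removes.
* **A season's shape**: 42 rostered players, 196 trainings + 74 games
  over 68 scheduled weeks, squads of 14 (games) / 20 (trainings) drawn
  with a core of regulars, which reproduces the heavy dispersion of
  per-player game counts seen in real cohorts (~25 ± 12 game profiles
  per player). Default durations are per-player *active* recording
  times — 60 min for games, 45 min for trainings — since few players log
  a full match of locomotion.

Each trace is generated from a seed derived from the season seed and the
(session, player) indices, so datasets are byte-reproducible and
generating only the games yields identical game traces.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: autocorrelated and heteroscedastic
GNSS error (HDOP excursions, multipath), positional (x, y) structure and
tactical constraints, within-session fatigue (the envelope is constant
across a session up to $E$), correlated squad selection (injuries,
suspensions), and any coupling between training load and capacity drift.
The comparison of prediction *tasks* is therefore a statement about the
pipeline's behaviour under a known, plausible world, not a reproduction
of any club's numbers.

## Pooling past sessions

Per-game predictors pool the last $L = 5$ sessions preceding the game
(`build_design_matrix()`), either by arithmetic mean or by softmax
exponential decay over the days-before-game vector $t$:

$$w_j = \frac{e^{-\beta t_j}}{\sum_k e^{-\beta t_k}}.$$

$t$ is measured in calendar days (session frequency is heterogeneous, so
session index would distort recency). $\beta$ is a hyperparameter with
no canonical value; the experiment selects it from
$\{0.1, 0.3, 0.5, 1.0\}$ per day on a chronological validation tail of
the training rows. Windows shorter than $L$ are kept by default (else
early-season games vanish); a strict mode drops them. The two pooling
operators share one weighted-sum code path, so $\beta = 0$ reproduces
the mean exactly, not merely to rounding.

## Signal features and selection

`extract_features()` computes a declared 27-feature catalogue from the
raw velocity signal: 18 time-domain statistics (moments, quantiles,
autocorrelations at lags 1/10/50, mean crossings, streaks, energy) and 9
spectral features from the one-sided DFT (centroid, variance, total
energy normalised so that it equals $\sum x^2 / n$ — the Parseval
identity fixes the convention — band energy fractions over
$[0, 0.1)$, $[0.1, 0.5)$, $[0.5, 1)$ and $[1, \text{Nyquist}]$ Hz, and
the dominant non-DC peak). Stationarity can be checked with a plain
Dickey-Fuller test (constant, no augmentation lags; tabulated 5%
critical values at the nearest sample size). Feature selection
(`select_top_k()`) ranks by univariate F-test p value
($F = r^2(n-2)/(1-r^2)$), with deterministic tie-breaking, and is always
computed on training rows only so held-out games never influence it.

## Prediction models

**Ridge** (`fit_ridge()`): features are z-scored, the intercept is
unpenalized, and coefficients solve
$(X^\top X + \lambda I)\beta = X^\top y$ in standardized space. When
$\lambda$ is not given it is selected on a $10^{-3}..10^3$ log grid by
forward-chaining cross-validation: validation blocks are always later in
time than every training row, because the experiment's holdout is
chronological and shuffled folds would leak.

**Forecasting** (`forecast_series()`): uni-modal baselines on the
games-only coefficient series — naive, drift, classic Theta, a
FourTheta-style generalisation ($\theta$ tuned over $\{1,2,3,4\}$ on a
validation tail), and an FFT family. Two implementation notes:

* *Theta.* The classic method extrapolates the OLS trend line ($Z_0$)
  and simple-exponential-smooths the doubled-curvature line
  $Z_2 = 2x - Z_0$ ($\alpha$ on an SSE grid), averaging the two. A
  known property of this construction is that it extrapolates only
  *half* of a deterministic trend (it is equivalent to SES with drift
  $b/2$); on an exact line the forecast falls short by $b\,h/2$. The
  package implements the classic method faithfully and its tests assert
  this actual behaviour rather than an idealised one.
* *FFT.* Selecting the top-$K$ spectral peaks of the detrended series
  and extrapolating "trend + harmonics" with raw FFT amplitudes fails
  even on a pure sinusoid, because OLS fits a spurious trend to any
  finite oscillation sample and its extrapolation dominates the error.
  The package instead uses the FFT only to *select* frequencies and then
  re-estimates trend and harmonic coefficients jointly by least squares
  (harmonic regression), which continues sinusoids essentially exactly.

Ensembles (`ensemble_average()`) use equal weights by default —
performance-based weighting is available but the default stays
assumption-free. Model families that need large per-player histories
(recurrent networks, vector forecasters) are out of scope; the
`forecast_series()` interface (ordered series in, $h$-step forecast out)
is the plug-in point, and a `min_obs` eligibility filter (e.g. 40
observations) supports long-series-only analyses.

## Evaluation design

All tasks are scored with MAPE on the *fraction* scale, on the identical
chronological per-player split: the last 20% of each eligible player's
games are the test set, never shuffled; eligibility defaults to 10 valid
game profiles so that every training series supports the theta/FFT
families. MAPE is averaged per player first and then across players
(a pooled variant is available), so heavily-selected regulars do not
dominate. The experiment enforces that every task scores exactly the
same (player, game) keys, and its summary table is recomputable from the
row-level predictions.

Task differences are tested with a seeded paired bootstrap over players
(`paired_bootstrap_compare()`): players are resampled with replacement
and the difference in mean per-player MAPE recomputed, giving a
percentile CI and two-sided p. This deliberately replaces
repeated-measures ANOVA with post-hoc adjustment: the bootstrap makes no
sphericity or normality assumptions, respects the player as the sampling
unit, and serves the same decision — is one task's error distinguishable
from another's?

Because slope and intercept live on very different ranges, cross-target
statements use `rescale_targets()`, an affine map of the slope series
onto the intercept range whose parameters are estimated on training rows
only.

## Problem sizes used by the test suite

The package's own checks run, as their standard conditions: 50 clean and
50 noisy single sessions for envelope recovery; five full-season
generations (games only) for calibration of the coefficient means; three
full seasons with the complete task comparison for the ordering checks;
and small parameterised instances for every numerical oracle. These
sizes are the package's choices for routine validation; all scale up via
`season_config()`.

## Known limitations

* The extraction accuracy statements assume the generator's bout
  structure; a real session with no maximal efforts above 3 m/s yields
  (correctly) an invalid profile, and sparse high-velocity coverage
  widens slope error.
* Velocity noise enters bin maxima asymmetrically (maxima of noisy
  samples are upward-biased); the 1 Hz zero-phase filter keeps this bias
  to a few percent at sd 0.1 m/s, but heavier noise would require either
  a lower cut-off or quantile-based bin summaries.
* Classic Theta under-extrapolates deterministic trends by half (see
  above); on slowly drifting coefficient series this is mild, but it is
  inherent to the method.
* The control task's advantage depends on session-level effort
  expression being visible in same-day features; in worlds where
  capacities are static and features are noisy, pooled history can win
  instead. The generator makes this mechanism explicit and configurable
  (`game_effort`, `training_effort`).
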