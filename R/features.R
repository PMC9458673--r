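#' Extract time- and frequency-domain features from a velocity signal
#'
#' A declared catalogue of 27 scalar features computed directly from the
#' raw velocity series: 18 time-domain statistics and 9 features of the
#' one-sided discrete Fourier spectrum. Spectral energy is normalised so
#' that the total equals `sum(v^2) / n` (Parseval identity); band energy
#' fractions over [0, 0.1), [0.1, 0.5), [0.5, 1.0) and [1.0, Nyquist] Hz
#' sum to one. The dominant peak is the largest non-DC spectral magnitude.
#'
#' @param v Numeric velocity series (>= 64 samples) or a
#'   [session_trace()].
#' @param rate Sampling rate in Hz (taken from the trace if given one).
#' @return Named numeric vector of 27 features.
#' @examples
#' extract_features(sin(2 * pi * 0.25 * (0:999) / 10) + 2, rate = 10)["dominant_freq_hz"]
#' @export
extract_features <- function(v, rate = 10) {
  if (inherits(v, "session_trace")) {
    rate <- v$rate
    v <- v$v
  }
  n <- length(v)
  if (n < 64) stop(sprintf("need at least 64 samples, got %d", n))
  m <- mean(v)
  dv <- v - m
  s2 <- sum(dv^2)
  acf_at <- function(lag) {
    if (s2 == 0 || lag >= n) return(0)
    sum(dv[seq_len(n - lag)] * dv[(lag + 1):n]) / s2
  }
  above <- v > m
  streak <- if (any(above)) {
    r <- rle(above); max(r$lengths[r$values])
  } else 0L
  crossings <- sum(diff(above) != 0L)
  sdv <- sqrt(s2 / (n - 1))
  skew <- if (s2 > 0) mean(dv^3) / (sqrt(s2 / n))^3 else 0
  kurt <- if (s2 > 0) mean(dv^4) / (s2 / n)^2 - 3 else 0

  ## one-sided spectrum; energy normalised so the total obeys Parseval
  X <- fft(v)
  half <- seq_len(floor(n / 2) + 1L)
  en <- Mod(X[half])^2 / n^2
  dup <- half > 1L & (half - 1L) < n - (half - 1L)  # bins with a conjugate twin
  en[dup] <- 2 * en[dup]
  freq <- (half - 1L) * rate / n
  etot <- sum(en)
  centroid <- if (etot > 0) sum(freq * en) / etot else 0
  spec_var <- if (etot > 0) sum((freq - centroid)^2 * en) / etot else 0
  edges <- c(0, 0.1, 0.5, 1.0, rate / 2 + 1e-9)
  band <- vapply(seq_len(4), function(b)
    sum(en[freq >= edges[b] & freq < edges[b + 1]]), 0)
  bandfrac <- if (etot > 0) band / etot else c(1, 0, 0, 0)
  nd <- half[-1L]
  mag <- Mod(X[nd]) / n
  peak <- if (length(mag) && max(mag) > 0) which.max(mag) else NA_integer_

  vs <- sort(v)                       # one sort serves median and quantiles
  qat <- function(p) {                # type-7 quantile on the sorted vector
    hh <- (n - 1) * p + 1
    lo <- floor(hh)
    vs[lo] + (hh - lo) * (vs[min(lo + 1, n)] - vs[lo])
  }
  sumsq <- sum(v^2)
  c(mean = m, sd = sdv, median = qat(0.5), min = vs[1], max = vs[n],
    abs_energy = sumsq,
    mean_abs_change = mean(abs(diff(v))),
    n_mean_crossings = crossings,
    autocorr_lag1 = acf_at(1L), autocorr_lag10 = acf_at(10L),
    autocorr_lag50 = acf_at(50L),
    count_above_mean = sum(above),
    longest_streak_above_mean = streak,
    rms = sqrt(sumsq / n), skewness = skew, kurtosis = kurt,
    q10 = qat(0.1), q90 = qat(0.9),
    spectral_centroid_hz = centroid, spectral_variance = spec_var,
    spectral_energy = etot,
    band_frac_0_0.1 = bandfrac[1], band_frac_0.1_0.5 = bandfrac[2],
    band_frac_0.5_1 = bandfrac[3], band_frac_1_nyq = bandfrac[4],
    dominant_amp = if (is.na(peak)) 0 else mag[peak],
    dominant_freq_hz = if (is.na(peak)) 0 else (nd[peak] - 1L) * rate / n)
}

## 5% critical values of the Dickey-Fuller tau statistic, constant case
df_crit_5pct <- data.frame(n = c(25, 50, 100, 250, 500, 1e9),
                           crit = c(-3.00, -2.93, -2.89, -2.88, -2.87, -2.86))

#' Dickey-Fuller unit-root test (constant, no lags)
#'
#' Plain Dickey-Fuller regression of `diff(x)` on `x[t-1]` and a
#' constant; the statistic is the t-ratio of the lagged-level
#' coefficient, compared with the tabulated 5% critical value for the
#' nearest tabulated sample size. Rejection indicates stationarity.
#'
#' @param x Numeric series (>= 25 observations, non-constant).
#' @return List with `statistic`, `crit_5pct` and logical `reject_at_5pct`.
#' @examples
#' set.seed(1)
#' dickey_fuller_stat(rnorm(200))$reject_at_5pct  # white noise: TRUE
#' @export
dickey_fuller_stat <- function(x) {
  n <- length(x)
  if (n < 25) stop("need at least 25 observations")
  if (var(x) == 0) stop("constant series: no variation to test")
  dx <- diff(x)
  xl <- x[-n]
  fit <- lm(dx ~ xl)
  sm <- summary(fit)$coefficients
  stat <- sm["xl", "t value"]
  crit <- df_crit_5pct$crit[which.min(abs(df_crit_5pct$n - (n - 1)))]
  list(statistic = unname(stat), crit_5pct = crit,
       reject_at_5pct = unname(stat < crit))
}

#' Univariate F test of association between a feature and a target
#'
#' The squared Pearson correlation converted to an F statistic,
#' `F = r^2 (n - 2) / (1 - r^2)`, with the p value from the F(1, n-2)
#' survival function. Identical to the overall F test of the simple
#' linear regression of `y` on `x`.
#'
#' @param x Feature column.
#' @param y Target.
#' @return List with `F` and `p`. A constant `x` yields `F = 0, p = 1`
#'   with a warning.
#' @export
f_test_univariate <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("'x' and 'y' lengths differ")
  if (n < 3) stop("need at least 3 observations")
  if (var(x) == 0) {
    warning("constant feature: F = 0, p = 1")
    return(list(F = 0, p = 1))
  }
  r2 <- stats::cor(x, y)^2
  if (r2 >= 1) {
    F <- Inf
    p <- .Machine$double.xmin
  } else {
    F <- r2 * (n - 2) / (1 - r2)
    p <- max(pf(F, 1, n - 2, lower.tail = FALSE), .Machine$double.xmin)
  }
  list(F = F, p = p)
}

#' Select the top-k features by univariate F tests
#'
#' Ranks features by ascending p value (ties broken by descending F,
#' then by feature name) and retains the best `k`. Intended to be run on
#' training rows only, so the held-out games never influence selection.
#'
#' @param X Numeric matrix or data frame of features (named columns).
#' @param y Target vector.
#' @param k Number of features to retain (default 10).
#' @return A `selection_report` data frame with columns `feature`, `F`,
#'   `p`, `rank` and `retained`, ordered by rank.
#' @examples
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' select_top_k(X, X[, 1] + rnorm(20, 0, 0.1), k = 2)
#' @export
select_top_k <- function(X, y, k = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  res <- lapply(seq_len(ncol(X)), function(j)
    suppressWarnings(f_test_univariate(X[, j], y)))
  Fv <- vapply(res, `[[`, 0, "F")
  pv <- vapply(res, `[[`, 0, "p")
  o <- order(pv, -Fv, colnames(X), method = "radix")
  out <- data.frame(feature = colnames(X)[o], F = Fv[o], p = pv[o],
                    rank = seq_len(ncol(X)),
                    retained = seq_len(ncol(X)) <= min(k, ncol(X)),
                    stringsAsFactors = FALSE)
  class(out) <- c("selection_report", "data.frame")
  out
}
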