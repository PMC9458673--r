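#' Forecast an ordered coefficient series
#'
#' Uni-modal forecasting baselines for per-athlete series of fitted
#' profile coefficients (games only, in chronological order):
#' \describe{
#'   \item{naive}{last observed value.}
#'   \item{drift}{last value plus the mean first difference per step.}
#'   \item{theta}{classic Theta with theta = 2: the theta-0 line is the
#'     OLS trend extrapolation; the theta-2 line `2 x - trend` is
#'     forecast by simple exponential smoothing (alpha chosen on an SSE
#'     grid 0.01-0.99); the forecast is the equal-weight average of the
#'     two.}
#'   \item{fourtheta}{the theta generalisation with theta tuned over
#'     \{1, 2, 3, 4\} on a validation tail; the combination weights are
#'     `1/theta` on the smoothed theta-line and `1 - 1/theta` on the
#'     trend, which reduces to the classic average at theta = 2.}
#'   \item{fft}{OLS detrend, keep the `fft_k` largest-magnitude non-DC
#'     harmonics of the residual spectrum, extrapolate trend plus
#'     retained harmonics.}
#'   \item{ensemble}{average of the other families (see
#'     [ensemble_average()]).}
#' }
#'
#' @param x Numeric series. Minimum length 3 (naive, drift) or 8 (theta,
#'   fourtheta, fft).
#' @param h Forecast horizon, >= 1.
#' @param family Model family.
#' @param theta Theta parameter for `family = "theta"` (default 2).
#' @param fft_k Retained harmonics for the FFT family (default 3).
#' @param min_obs Optional eligibility filter: error out unless
#'   `length(x) >= min_obs` (e.g. 40 for long-series-only analyses).
#' @return Numeric vector of `h` forecasts.
#' @examples
#' forecast_series(1:20, h = 3, family = "drift")  # 21 22 23
#' @export
forecast_series <- function(x, h = 1,
                            family = c("naive", "drift", "theta",
                                       "fourtheta", "fft", "ensemble"),
                            theta = 2, fft_k = 3, min_obs = NULL) {
  family <- match.arg(family)
  x <- as.numeric(x)
  n <- length(x)
  if (h < 1) stop("'h' must be >= 1")
  if (!is.null(min_obs) && n < min_obs)
    stop(sprintf("series has %d < %d observations", n, min_obs))
  minlen <- c(naive = 3, drift = 3, theta = 8, fourtheta = 8, fft = 8,
              ensemble = 8)[[family]]
  if (n < minlen)
    stop(sprintf("family '%s' needs at least %d observations, got %d",
                 family, minlen, n))
  switch(family,
         naive = rep(x[n], h),
         drift = x[n] + mean(diff(x)) * seq_len(h),
         theta = theta_forecast(x, h, theta),
         fourtheta = fourtheta_forecast(x, h),
         fft = fft_forecast(x, h, fft_k),
         ensemble = ensemble_average(list(
           naive = forecast_series(x, h, "naive"),
           drift = forecast_series(x, h, "drift"),
           theta = forecast_series(x, h, "theta"),
           fourtheta = forecast_series(x, h, "fourtheta"),
           fft = forecast_series(x, h, "fft"))))
}

## simple exponential smoothing: SSE-optimal alpha on a grid, flat forecast
ses_forecast <- function(x, h, alpha_grid = seq(0.01, 0.99, by = 0.01)) {
  n <- length(x)
  best <- NULL
  best_sse <- Inf
  for (a in alpha_grid) {
    l <- x[1]
    sse <- 0
    for (t in 2:n) {
      e <- x[t] - l
      sse <- sse + e^2
      l <- l + a * e
    }
    if (sse < best_sse) {
      best_sse <- sse
      best <- l
    }
  }
  rep(best, h)
}

## theta decomposition: trend line Z0, theta-line Ztheta = theta*x +
## (1-theta)*Z0; recombination weights (1/theta, 1-1/theta) reproduce x
## in-sample and the classic equal-weight average at theta = 2
theta_forecast <- function(x, h, theta = 2) {
  if (theta < 0) stop("'theta' must be >= 0")
  n <- length(x)
  tt <- seq_len(n)
  fit <- lm(x ~ tt)
  z0_in <- fitted(fit)
  z0_out <- coef(fit)[[1]] + coef(fit)[[2]] * (n + seq_len(h))
  if (theta == 0) return(as.numeric(z0_out))
  zt <- theta * x + (1 - theta) * z0_in
  zt_fc <- ses_forecast(zt, h)
  as.numeric((1 / theta) * zt_fc + (1 - 1 / theta) * z0_out)
}

## theta tuned on the last ~20% of the series
fourtheta_forecast <- function(x, h, grid = c(1, 2, 3, 4)) {
  n <- length(x)
  n_val <- max(2L, round(0.2 * n))
  head_x <- x[seq_len(n - n_val)]
  val <- x[(n - n_val + 1):n]
  errs <- vapply(grid, function(th) {
    fc <- theta_forecast(head_x, n_val, th)
    mean(abs(val - fc))
  }, 0)
  theta_forecast(x, h, grid[which.min(errs)])
}

## frequency selection on the detrended spectrum, then a joint harmonic
## regression (trend + retained cos/sin terms) so the trend and the
## harmonics do not leak into each other; extrapolate the fitted model
fft_forecast <- function(x, h, k = 3) {
  n <- length(x)
  tt <- seq_len(n)
  trend <- lm(x ~ tt)
  X <- fft(residuals(trend))
  half <- 2:(floor(n / 2) + 1)            # non-DC one-sided bins
  mag <- Mod(X[half])
  keep <- half[order(mag, decreasing = TRUE)[seq_len(min(k, length(half)))]]
  freqs <- (keep - 1) / n
  basis <- function(t) {
    M <- cbind(1, t)
    for (fr in freqs)
      M <- cbind(M, cos(2 * pi * fr * t), sin(2 * pi * fr * t))
    M
  }
  B <- basis(tt)
  cf <- qr.coef(qr(B), x)
  cf[is.na(cf)] <- 0                      # collinear terms (e.g. Nyquist sin)
  as.numeric(basis(n + seq_len(h)) %*% cf)
}

#' Average several forecasts into an ensemble
#'
#' Unweighted mean by default; optionally weighted (e.g. by inverse
#' validation MAPE), with weights normalised internally.
#'
#' @param forecasts List of >= 2 numeric forecast vectors with a common
#'   horizon.
#' @param weights Optional non-negative weights, one per forecast.
#' @return Numeric vector of the common horizon.
#' @examples
#' ensemble_average(list(c(1, 1), c(3, 3)))  # 2 2
#' @export
ensemble_average <- function(forecasts, weights = NULL) {
  if (length(forecasts) < 2) stop("need at least two forecasts")
  hs <- lengths(forecasts)
  if (length(unique(hs)) != 1) stop("forecast horizons differ")
  M <- do.call(rbind, forecasts)
  if (is.null(weights)) return(colMeans(M))
  if (length(weights) != nrow(M) || any(weights < 0))
    stop("'weights' must be non-negative, one per forecast")
  as.numeric(crossprod(weights / sum(weights), M))
}
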