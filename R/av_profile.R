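#' Maximal acceleration per velocity bin
#'
#' Groups acceleration samples by the velocity at which they occurred,
#' using left-closed bins `[k*w, (k+1)*w)` of width `w`, and retains the
#' maximal acceleration in each populated bin. Empty bins are omitted.
#'
#' @param v Velocity (m/s) aligned sample-by-sample with `a`.
#' @param a Acceleration samples (m/s^2), typically low-pass filtered.
#' @param bin_width Bin width in m/s (default 0.1).
#' @return A data frame with columns `bin_center` (m/s), `a_max` (m/s^2)
#'   and `n` (samples in the bin), ordered by velocity.
#' @examples
#' bin_max_acceleration(c(3.04, 3.06, 3.17), c(1.2, 1.5, 0.9))
#' @export
bin_max_acceleration <- function(v, a, bin_width = 0.1) {
  if (!length(v)) stop("empty input")
  if (length(v) != length(a)) stop("'v' and 'a' must have equal length")
  if (bin_width <= 0) stop("'bin_width' must be positive")
  idx <- as.integer(floor(v / bin_width))
  ## max per bin without per-group apply: sort by (bin, value); the last
  ## element of each run is the bin maximum
  o <- order(idx, a, method = "radix")
  io <- idx[o]
  ends <- cumsum(rle(io)$lengths)
  data.frame(bin_center = (io[ends] + 0.5) * bin_width,
             a_max = a[o][ends],
             n = diff(c(0L, ends)))
}

#' Fit the linear acceleration-velocity envelope to binned maxima
#'
#' Ordinary least squares of maximal acceleration on bin-center velocity,
#' restricted to bins strictly above `v_min` whose maximum exceeds
#' `a_min`. Bins whose maximal acceleration is not positive were never
#' visited while accelerating and carry no information about a maximal
#' acceleration envelope, so they are excluded by default.
#'
#' @param binned Data frame from [bin_max_acceleration()].
#' @param v_min Lower velocity limit of the fit, exclusive (default 3 m/s).
#' @param min_bins Minimum number of retained bins for a valid fit
#'   (default 10); with fewer bins the profile is flagged invalid and no
#'   coefficients are returned.
#' @param a_min Retain only bins with `a_max > a_min` (default 0).
#' @return An object of class `"av_profile"` with elements `slope` (1/s),
#'   `intercept` (m/s^2), `r_squared`, `n_bins_used`, `valid`, the fitting
#'   parameters, and the retained bins.
#' @export
fit_profile <- function(binned, v_min = 3, min_bins = 10, a_min = 0) {
  stopifnot(is.data.frame(binned),
            all(c("bin_center", "a_max") %in% names(binned)))
  keep <- binned$bin_center > v_min & binned$a_max > a_min
  used <- binned[keep, , drop = FALSE]
  out <- structure(list(slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, n_bins_used = nrow(used),
                        valid = FALSE, v_min = v_min, min_bins = min_bins,
                        a_min = a_min, bins = used,
                        player_id = NA_character_, session_id = NA_character_,
                        date = as.Date(NA), kind = NA_character_),
                   class = "av_profile")
  if (nrow(used) < min_bins) return(out)
  x <- used$bin_center
  y <- used$a_max
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  syy <- sum((y - my)^2)
  out$slope <- slope
  out$intercept <- intercept
  out$r_squared <- if (syy > 0) max(0, 1 - sum(res^2) / syy) else 1
  out$valid <- TRUE
  out
}

#' Fit an acceleration-velocity profile to a velocity trace
#'
#' The core estimator of the package. Runs the profiling pipeline on one
#' session: backward-difference acceleration ([compute_acceleration()]),
#' first-order Butterworth low-pass filtering ([lowpass_filter()]),
#' per-velocity-bin maximal acceleration ([bin_max_acceleration()]) and an
#' ordinary least-squares envelope fit above `v_min` ([fit_profile()]).
#' The fitted intercept estimates the theoretical maximal acceleration
#' (m/s^2) and the slope its decline with velocity (1/s); `-intercept /
#' slope` estimates maximal running velocity.
#'
#' Acceleration sample `i` (the step from `v[i]` to `v[i+1]`) is paired
#' with the velocity `v[i]` at which the step began. For maximal efforts
#' whose acceleration is a function of current velocity this pairing is
#' exact at the sample resolution, whereas pairing with the end-of-step
#' velocity overstates the envelope by a factor `1 + intercept /
#' (rate * v_max)` (about 5% at 10 Hz for elite sprinters).
#'
#' @param trace A [session_trace()], or a numeric velocity vector.
#' @param rate Sampling rate in Hz when `trace` is a bare vector.
#' @param filter A [filter_spec()]; default zero-phase 1 Hz.
#' @param bin_width Velocity bin width, m/s.
#' @param v_min Lower velocity bound of the envelope fit, m/s (exclusive).
#' @param min_bins Minimum retained bins for a valid profile.
#' @param a_min Minimum bin maximal acceleration for retention (m/s^2).
#' @return An object of class `"av_profile"`; see [fit_profile()].
#'   Methods: `print`, `summary`, `coef` (intercept, slope), `predict`
#'   (envelope acceleration at new velocities), `residuals` (bin
#'   residuals), `plot`, and `simulate` (a maximal-effort velocity trace
#'   consistent with the fitted envelope).
#' @examples
#' prof <- ground_truth_profile("p1", A0 = 4.72, V0 = 8.86)
#' tr <- simulate_session(prof, kind = "game", duration_s = 600,
#'                        config = season_config(noise_sd = 0), seed = 1)
#' fit <- av_profile(tr)
#' coef(fit)
#' @export
av_profile <- function(trace, rate = 10, filter = filter_spec(),
                       bin_width = 0.1, v_min = 3, min_bins = 10, a_min = 0) {
  meta <- list(player_id = NA_character_, session_id = NA_character_,
               date = as.Date(NA), kind = NA_character_)
  if (inherits(trace, "session_trace")) {
    meta <- trace[c("player_id", "session_id", "date", "kind")]
    rate <- trace$rate
    v <- trace$v
  } else {
    v <- as.numeric(trace)
  }
  a <- compute_acceleration(v, rate)
  af <- lowpass_filter(a, rate, filter)
  fit <- profile_from(v, af, bin_width, v_min, min_bins, a_min)
  fit[names(meta)] <- meta
  fit$rate <- rate
  fit$filter <- filter
  fit$bin_width <- bin_width
  fit
}

## binning + envelope fit on a precomputed filtered acceleration, shared
## with the season loop
profile_from <- function(v, af, bin_width = 0.1, v_min = 3, min_bins = 10,
                         a_min = 0) {
  vs <- v[-length(v)]  # start-of-step velocity, aligned with a
  if (any(vs > v_min)) {
    fit_profile(bin_max_acceleration(vs, af, bin_width),
                v_min = v_min, min_bins = min_bins, a_min = a_min)
  } else {
    fit_profile(data.frame(bin_center = numeric(), a_max = numeric(),
                           n = integer()),
                v_min = v_min, min_bins = min_bins, a_min = a_min)
  }
}

#' @export
print.av_profile <- function(x, ...) {
  cat("Acceleration-velocity profile\n")
  if (!is.na(x$player_id))
    cat(sprintf("  %s / %s (%s)\n", x$player_id, x$session_id,
                format(x$date)))
  if (x$valid) {
    cat(sprintf("  intercept %.3f m/s^2, slope %.4f 1/s  (v0 %.2f m/s)\n",
                x$intercept, x$slope, -x$intercept / x$slope))
    cat(sprintf("  r^2 %.4f over %d bins above %g m/s\n",
                x$r_squared, x$n_bins_used, x$v_min))
  } else {
    cat(sprintf("  invalid: only %d usable bins above %g m/s (need %d)\n",
                x$n_bins_used, x$v_min, x$min_bins))
  }
  invisible(x)
}

#' @export
summary.av_profile <- function(object, ...) {
  print(object)
  if (object$valid && nrow(object$bins)) {
    res <- residuals(object)
    cat(sprintf("  bin residuals: median %.3f, IQR [%.3f, %.3f] m/s^2\n",
                median(res), quantile(res, 0.25), quantile(res, 0.75)))
  }
  invisible(object)
}

#' @export
coef.av_profile <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.av_profile <- function(object, newdata = NULL, ...) {
  if (!object$valid) stop("cannot predict from an invalid profile")
  v <- if (is.null(newdata)) object$bins$bin_center else as.numeric(newdata)
  object$intercept + object$slope * v
}

#' @export
residuals.av_profile <- function(object, ...) {
  if (!object$valid) stop("no residuals for an invalid profile")
  object$bins$a_max - predict(object)
}

#' @export
plot.av_profile <- function(x, ...) {
  if (!nrow(x$bins)) stop("no bins to plot")
  plot(x$bins$bin_center, x$bins$a_max, pch = 16, cex = 0.7,
       xlab = "velocity (m/s)", ylab = "max acceleration (m/s^2)", ...)
  if (x$valid) abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}

#' @export
simulate.av_profile <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$valid) stop("cannot simulate from an invalid profile")
  gt <- ground_truth_profile(object$player_id,
                             A0 = object$intercept,
                             V0 = -object$intercept / object$slope)
  simulate_bout(gt, effort = 1, v_start = 0,
                v_target = 0.99 * gt$V0, rate = object$rate)
}
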