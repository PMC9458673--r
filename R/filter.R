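#' Specify the acceleration low-pass filter
#'
#' The profiling pipeline smooths the differenced velocity signal with a
#' first-order Butterworth low-pass filter before taking per-bin maxima.
#' Only the filter order 1 is supported, matching the profiling method;
#' the cut-off and the phase behaviour are configurable.
#'
#' @param order Filter order; must be 1.
#' @param cutoff_hz Cut-off frequency in Hz (default 1). Must be strictly
#'   below the Nyquist frequency of the signal it is applied to.
#' @param mode `"zero-phase"` (forward-backward pass, squared magnitude
#'   response, zero lag; the default, so filtered acceleration stays aligned
#'   with velocity) or `"causal"` (single forward pass).
#' @return An object of class `"filter_spec"`.
#' @examples
#' filter_spec()
#' filter_spec(cutoff_hz = 0.8, mode = "causal")
#' @export
filter_spec <- function(order = 1L, cutoff_hz = 1, mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  if (!identical(as.integer(order), 1L))
    stop("only first-order filters are supported (order = 1)")
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0)
    stop("'cutoff_hz' must be a single positive number")
  structure(list(order = 1L, cutoff_hz = cutoff_hz, mode = mode),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("First-order Butterworth low-pass: cutoff %g Hz, %s\n",
              x$cutoff_hz, x$mode))
  invisible(x)
}

#' Derive acceleration from a velocity series
#'
#' Backward difference of velocity scaled to physical units:
#' `a[i] = (v[i] - v[i-1]) * rate` (m/s^2). The output has one element
#' fewer than the input; element `i` is the acceleration over the step
#' ending at sample `i + 1` of `v`.
#'
#' @param v Numeric velocity series (m/s), or a [session_trace()].
#' @param rate Sampling rate in Hz (default 10). Ignored when `v` is a
#'   trace, which carries its own rate.
#' @param t Optional timestamp vector (s). When supplied it is checked for
#'   a uniform step consistent with `rate`; a non-uniform step raises an
#'   error naming the offending index.
#' @return Numeric acceleration series of length `length(v) - 1`.
#' @examples
#' compute_acceleration(c(3.0, 3.1, 3.3), rate = 10)  # 1, 2 m/s^2
#' @export
compute_acceleration <- function(v, rate = 10, t = NULL) {
  if (inherits(v, "session_trace")) {
    rate <- v$rate
    t <- v$t
    v <- v$v
  }
  if (length(v) < 2L) stop("need at least two velocity samples")
  if (!is.null(t)) {
    if (length(t) != length(v)) stop("'t' and 'v' lengths differ")
    dt <- diff(t)
    bad <- which(abs(dt - 1 / rate) > 1e-9)
    if (length(bad))
      stop(sprintf("non-uniform sampling at index %d (step %.6g s, expected %.6g s)",
                   bad[1] + 1L, dt[bad[1]], 1 / rate))
  }
  diff(v) * rate
}

## Discrete first-order Butterworth coefficients, via signal::butter.
butter1 <- function(cutoff_hz, rate) {
  if (cutoff_hz >= rate / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, rate / 2))
  bf <- signal::butter(1, cutoff_hz / (rate / 2))
  list(b = bf$b, a = bf$a)
}

## Single causal pass of the order-1 filter with given initial state.
## y[n] = b0 x[n] + b1 x[n-1] - a1 y[n-1]; zero initial conditions, like
## signal::filter.
pass1 <- function(x, cf) {
  n <- length(x)
  u <- cf$b[1] * x + cf$b[2] * c(0, x[-n])
  as.numeric(stats::filter(u, -cf$a[2], method = "recursive"))
}

#' Low-pass filter a signal
#'
#' Applies the first-order Butterworth filter described by a
#' [filter_spec()]. In `"causal"` mode a single forward pass is used
#' (gain 1/sqrt(2) at the cut-off). In `"zero-phase"` mode the signal is
#' filtered forward and backward, which squares the magnitude response
#' (gain 1/2 at the cut-off) and cancels the phase lag; the series is
#' mirror-padded at both ends to suppress edge transients.
#'
#' @param x Numeric series.
#' @param rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series, same length as `x`.
#' @examples
#' lowpass_filter(rep(2, 100), rate = 10)  # DC gain 1
#' @export
lowpass_filter <- function(x, rate = 10, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop("'spec' must be a filter_spec")
  n <- length(x)
  if (n < 4L) stop("series too short to filter")
  cf <- butter1(spec$cutoff_hz, rate)
  if (spec$mode == "causal") return(pass1(x, cf))
  ## zero-phase: odd (point-symmetric) mirror padding, forward then backward
  npad <- min(n - 1L, as.integer(ceiling(3 * rate / spec$cutoff_hz)))
  xp <- c(2 * x[1] - x[(npad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  y <- pass1(xp, cf)
  y <- rev(pass1(rev(y), cf))
  y[(npad + 1L):(npad + n)]
}
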