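#' Construct a session velocity trace
#'
#' A `session_trace` holds one session's uniformly sampled velocity signal
#' together with its metadata. Timestamps are implicit: sample `i` is at
#' `(i - 1) / rate` seconds.
#'
#' @param v Numeric velocity series (m/s), all values >= 0.
#' @param rate Sampling rate in Hz (default 10).
#' @param player_id,session_id Identifiers.
#' @param date Session date (`Date` or coercible).
#' @param kind `"game"` or `"training"`.
#' @return An object of class `"session_trace"`.
#' @examples
#' tr <- session_trace(rep(2, 100), player_id = "p1", session_id = "s1",
#'                     date = as.Date("2020-08-01"), kind = "training")
#' @export
session_trace <- function(v, rate = 10, player_id = NA_character_,
                          session_id = NA_character_, date = NA,
                          kind = c("training", "game")) {
  kind <- match.arg(kind)
  if (!is.numeric(v) || !length(v)) stop("'v' must be a non-empty numeric vector")
  if (any(!is.finite(v))) stop("'v' contains non-finite values")
  if (any(v < 0)) stop("'v' contains negative velocities")
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be positive")
  structure(list(v = as.numeric(v), rate = rate, t = NULL,
                 player_id = player_id, session_id = session_id,
                 date = as.Date(date), kind = kind),
            class = "session_trace")
}

#' @export
print.session_trace <- function(x, ...) {
  cat(sprintf("Session trace: %s / %s (%s, %s)\n", x$player_id, x$session_id,
              x$kind, format(x$date)))
  cat(sprintf("  %d samples at %g Hz (%.1f min), max speed %.2f m/s\n",
              length(x$v), x$rate, length(x$v) / x$rate / 60, max(x$v)))
  invisible(x)
}

#' Write / read a velocity trace as CSV
#'
#' Traces are exchanged as two-column CSV files with header
#' `time_s,velocity_mps`.
#'
#' @param trace A [session_trace()].
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [session_trace()] (metadata not stored in the file must be
#'   supplied via `...`, forwarded to [session_trace()]).
#' @param ... Metadata arguments for [session_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "session_trace"))
  df <- data.frame(time_s = (seq_along(trace$v) - 1) / trace$rate,
                   velocity_mps = trace$v)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "velocity_mps") %in% names(df)))
    stop("expected columns 'time_s' and 'velocity_mps'")
  dt <- diff(df$time_s)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6)
    stop("timestamps in file are not uniformly spaced")
  rate <- if (length(dt)) 1 / dt[1] else 10
  session_trace(df$velocity_mps, rate = round(rate, 6), ...)
}
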