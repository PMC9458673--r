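#' Mean pooling of a session-feature window
#'
#' Column-wise arithmetic mean of the features of the sessions in a
#' window.
#'
#' @param window_features Numeric matrix, one row per session.
#' @return Named numeric vector (one value per feature).
#' @examples
#' mean_pool(rbind(c(1, 2), c(3, 4)))  # 2 3
#' @export
mean_pool <- function(window_features) {
  window_features <- as.matrix(window_features)
  if (!nrow(window_features)) stop("empty window")
  ## same summation path as exponential_pool so the beta = 0 equivalence
  ## is exact, not merely within rounding
  pool_weighted(window_features,
                rep(1 / nrow(window_features), nrow(window_features)))
}

## shared weighted column sum
pool_weighted <- function(M, w) {
  setNames(as.numeric(crossprod(w, M)), colnames(M))
}

#' Softmax exponential-decay weights
#'
#' Weights `w_j = exp(-beta * t_j) / sum_k exp(-beta * t_k)` over the
#' days-before-game vector `t`. More recent sessions (smaller `t`) get
#' larger weights; `beta = 0` gives uniform weights. The smallest
#' `beta * t` is subtracted before exponentiation for numerical
#' stability.
#'
#' @param t Non-negative days-before-game vector.
#' @param beta Decay scale, >= 0 (per day).
#' @return Weights summing to one.
#' @examples
#' softmax_weights(c(1, 2), beta = 0.5)
#' @export
softmax_weights <- function(t, beta) {
  if (length(beta) != 1L || beta < 0) stop("'beta' must be a single value >= 0")
  if (any(t < 0)) stop("'t' must be non-negative")
  z <- -beta * t
  e <- exp(z - max(z))
  e / sum(e)
}

#' Exponentially weighted pooling of a session-feature window
#'
#' Weighted column sums with [softmax_weights()]; at `beta = 0` this is
#' exactly [mean_pool()].
#'
#' @inheritParams mean_pool
#' @param t Days before the target game, one value per window row.
#' @param beta Decay scale, >= 0.
#' @return Named numeric vector.
#' @export
exponential_pool <- function(window_features, t, beta) {
  window_features <- as.matrix(window_features)
  if (!nrow(window_features)) stop("empty window")
  if (length(t) != nrow(window_features))
    stop("length of 't' must match the number of window rows")
  pool_weighted(window_features, softmax_weights(t, beta))
}

#' Build the pooled per-game design matrix
#'
#' For each game with a fitted profile, pools the features of the last
#' `L` sessions (training or game) strictly preceding the game into one
#' predictor row, by mean or exponential softmax weighting of the
#' days-before-game vector. Windows shorter than `L` are kept unless
#' `strict`; games with no preceding session are excluded.
#'
#' @param feature_table Data frame with `player_id`, `session_id`, `date`
#'   and feature columns (e.g. `season$summaries` or `season$features`).
#' @param profile_table Data frame of game profiles with `player_id`,
#'   `session_id`, `date`, `slope`, `intercept` (e.g. `season$profiles`).
#'   Invalid profiles are dropped.
#' @param L Window size (default 5 sessions).
#' @param method `"mean"` or `"exponential"`.
#' @param beta Decay scale for exponential pooling (per day).
#' @param strict Drop games with fewer than `L` predecessors.
#' @return List with `X` (pooled feature matrix), `targets` (data frame
#'   with `player_id`, `game_id`, `date`, `slope`, `intercept`),
#'   `windows` (list of per-game window metadata) and `excluded` (game
#'   ids with empty windows).
#' @export
build_design_matrix <- function(feature_table, profile_table, L = 5,
                                method = c("mean", "exponential"),
                                beta = 0.3, strict = FALSE) {
  method <- match.arg(method)
  need <- c("player_id", "session_id", "date")
  stopifnot(all(need %in% names(feature_table)),
            all(need %in% names(profile_table)))
  fcols <- setdiff(names(feature_table), c(need, "kind"))
  games <- profile_table
  if ("valid" %in% names(games))
    games <- games[games$valid, , drop = FALSE]
  ## per-player chronological views, scanned once per game
  ft <- feature_table[order(feature_table$player_id, feature_table$date), ,
                      drop = FALSE]
  by_player <- split(seq_len(nrow(ft)), ft$player_id)
  Fmat <- as.matrix(ft[, fcols, drop = FALSE])
  rows <- vector("list", nrow(games))
  wins <- vector("list", nrow(games))
  excluded <- character(0)
  for (i in seq_len(nrow(games))) {
    g <- games[i, ]
    pid <- by_player[[g$player_id]]
    pid <- pid[ft$date[pid] < g$date]
    if (!length(pid) || (strict && length(pid) < L)) {
      excluded <- c(excluded, g$session_id)
      next
    }
    win <- tail(pid, L)
    t_days <- as.numeric(g$date - ft$date[win])
    M <- Fmat[win, , drop = FALSE]
    x <- if (method == "mean") mean_pool(M) else
      exponential_pool(M, t_days, beta)
    rows[[i]] <- x
    wins[[i]] <- list(game_id = g$session_id,
                      sessions = ft$session_id[win], t_days = t_days)
  }
  keep <- !vapply(rows, is.null, TRUE)
  X <- do.call(rbind, rows[keep])
  targets <- data.frame(player_id = games$player_id[keep],
                        game_id = games$session_id[keep],
                        date = games$date[keep],
                        slope = games$slope[keep],
                        intercept = games$intercept[keep],
                        stringsAsFactors = FALSE)
  list(X = X, targets = targets, windows = wins[keep],
       method = method, beta = if (method == "exponential") beta else NA_real_,
       L = L, excluded = excluded)
}
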