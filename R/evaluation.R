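#' Mean absolute percentage error
#'
#' `mean(|y_true - y_pred| / |y_true|)`, reported as a fraction (0.115
#' means 11.5%). Zero true values make the measure undefined and raise
#' an error naming the offending rows.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return A single non-negative fraction.
#' @examples
#' mape(c(2, 4), c(1, 4))  # 0.25
#' @export
mape <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  zero <- which(y_true == 0)
  if (length(zero))
    stop("zero true values at rows: ", paste(head(zero, 5), collapse = ", "))
  mean(abs(y_true - y_pred) / abs(y_true))
}

#' Linearly re-scale the slope series onto the intercept range
#'
#' Slope and intercept coefficients live on very different ranges, so
#' errors on them are not directly comparable. This maps the slope
#' series affinely onto the intercept series' range (train-range min to
#' min, max to max), with the mapping parameters estimated on training
#' rows only and reapplied elsewhere.
#'
#' @param slope_series,intercept_series Numeric vectors (>= 2 distinct
#'   values each among training rows).
#' @param train Indices of the training rows (default: all).
#' @return List with `slope_rescaled`, and the affine parameters `a`,
#'   `b` such that `slope_rescaled = a + b * slope`.
#' @examples
#' rescale_targets(c(-0.6, -0.5, -0.4), c(4, 4.5, 5))$slope_rescaled
#' @export
rescale_targets <- function(slope_series, intercept_series,
                            train = seq_along(slope_series)) {
  rs <- range(slope_series[train])
  ri <- range(intercept_series[train])
  if (diff(rs) == 0 || diff(ri) == 0)
    stop("degenerate range: cannot re-scale")
  b <- diff(ri) / diff(rs)
  a <- ri[1] - b * rs[1]
  list(slope_rescaled = a + b * slope_series, a = a, b = b)
}

## per-player-then-average (default) or pooled MAPE over prediction rows
summarise_mape <- function(rows, aggregation = c("per_player", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "pooled") return(mape(rows$y_true, rows$y_pred))
  ape <- abs(rows$y_true - rows$y_pred) / abs(rows$y_true)
  mean(tapply(ape, rows$player_id, mean))
}

#' Paired bootstrap comparison of two tasks' errors
#'
#' Resamples players with replacement and recomputes the difference in
#' mean per-player MAPE between two prediction-row sets sharing the same
#' (player, game) keys, giving a percentile confidence interval and a
#' two-sided bootstrap p value.
#'
#' @param rows_a,rows_b Data frames with columns `player_id`, `game_id`,
#'   `y_true`, `y_pred` covering identical keys.
#' @param B Bootstrap replicates.
#' @param seed Seed for the resampling.
#' @param conf Confidence level of the percentile interval.
#' @return List with `mean_diff` (a minus b), `ci`, `p`, `B`.
#' @export
paired_bootstrap_compare <- function(rows_a, rows_b, B = 2000, seed = 1,
                                     conf = 0.95) {
  key_a <- paste(rows_a$player_id, rows_a$game_id)
  key_b <- paste(rows_b$player_id, rows_b$game_id)
  if (!setequal(key_a, key_b))
    stop("prediction rows do not share the same (player, game) keys")
  rows_b <- rows_b[match(key_a, key_b), , drop = FALSE]
  ape_a <- abs(rows_a$y_true - rows_a$y_pred) / abs(rows_a$y_true)
  ape_b <- abs(rows_b$y_true - rows_b$y_pred) / abs(rows_b$y_true)
  pa <- tapply(ape_a, rows_a$player_id, mean)
  pb <- tapply(ape_b, rows_a$player_id, mean)
  np <- length(pa)
  if (np < 5) stop("fewer than 5 shared players: refusing to bootstrap")
  d0 <- mean(pa) - mean(pb)
  d <- with_seed(seed, {
    idx <- matrix(sample.int(np, np * B, replace = TRUE), nrow = B)
    apply(idx, 1, function(i) mean(pa[i]) - mean(pb[i]))
  })
  alpha <- (1 - conf) / 2
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  list(mean_diff = d0, ci = unname(quantile(d, c(alpha, 1 - alpha))),
       p = max(p, 1 / B), B = B)
}

## chronological per-player split of the valid game profiles; a game needs
## at least one preceding session to be predictable from history
eval_split <- function(season, split = 0.8, min_games = 10) {
  pr <- season$profiles[season$profiles$valid, , drop = FALSE]
  sm <- season$summaries
  keep <- logical(nrow(pr))
  for (i in seq_len(nrow(pr)))
    keep[i] <- any(sm$player_id == pr$player_id[i] & sm$date < pr$date[i])
  pr <- pr[keep, , drop = FALSE]
  pr <- pr[order(pr$player_id, pr$date), , drop = FALSE]
  counts <- table(pr$player_id)
  eligible <- names(counts)[counts >= min_games]
  pr <- pr[pr$player_id %in% eligible, , drop = FALSE]
  if (!nrow(pr)) stop("no player has enough games for evaluation")
  pr$is_test <- FALSE
  for (p in eligible) {
    idx <- which(pr$player_id == p)
    n_test <- max(1L, length(idx) - floor(split * length(idx)))
    pr$is_test[tail(idx, n_test)] <- TRUE
  }
  pr
}

## ridge prediction rows for one feature table / pooling method / scope
ridge_task_rows <- function(games, X, target = c("intercept", "slope"),
                            scope = c("G", "I"), k = 10) {
  target <- match.arg(target)
  scope <- match.arg(scope)
  y <- games[[target]]
  run_one <- function(rows) {
    tr <- rows[!games$is_test[rows]]
    te <- rows[games$is_test[rows]]
    if (length(tr) < 3 || !length(te)) return(NULL)
    sel <- select_top_k(X[tr, , drop = FALSE], y[tr], k = k)
    feats <- sel$feature[sel$retained]
    fit <- suppressWarnings(
      fit_ridge(X[tr, feats, drop = FALSE], y[tr], dates = games$date[tr]))
    data.frame(player_id = games$player_id[te],
               game_id = games$game_id[te],
               y_true = y[te],
               y_pred = predict(fit, X[te, feats, drop = FALSE]),
               stringsAsFactors = FALSE)
  }
  out <- if (scope == "G") {
    run_one(seq_len(nrow(games)))
  } else {
    do.call(rbind, lapply(split(seq_len(nrow(games)), games$player_id),
                          run_one))
  }
  if (is.null(out)) stop("no predictable rows for this task")
  rownames(out) <- NULL
  out
}

## pick the softmax decay on a chronological validation tail of the train rows
select_beta <- function(games, X_by_beta, target, k = 10) {
  tr <- which(!games$is_test)
  if (length(tr) < 10) return(names(X_by_beta)[1])
  n_val <- max(2L, round(0.2 * length(tr)))
  sub_tr <- tr[seq_len(length(tr) - n_val)]
  sub_va <- tr[(length(tr) - n_val + 1):length(tr)]
  y <- games[[target]]
  errs <- vapply(X_by_beta, function(X) {
    sel <- select_top_k(X[sub_tr, , drop = FALSE], y[sub_tr], k = k)
    feats <- sel$feature[sel$retained]
    fit <- suppressWarnings(fit_ridge(X[sub_tr, feats, drop = FALSE],
                                      y[sub_tr],
                                      dates = games$date[sub_tr]))
    mean(abs(y[sub_va] - predict(fit, X[sub_va, feats, drop = FALSE])))
  }, 0)
  names(X_by_beta)[which.min(errs)]
}

#' Same-day control regression
#'
#' The control task predicts a game's A-V coefficients from that same
#' game's summary features - an upper bound on predictability, since no
#' forecasting is involved. Ridge regression with univariate top-k
#' feature selection on a chronological 80/20 holdout.
#'
#' @param season An `"av_season"` (or anything with `$profiles` and
#'   `$summaries` in the same layout).
#' @param scope `"G"` (one model over the pooled group) or `"I"`
#'   (per-player models).
#' @param split Chronological train fraction.
#' @param min_games Minimum valid game profiles per included player.
#' @param k Features retained by selection.
#' @return List with `rows` (per-game predictions for both targets) and
#'   `mape` (named per-target summary, per-player aggregation).
#' @export
run_control_task <- function(season, scope = c("G", "I"), split = 0.8,
                             min_games = 5, k = 10) {
  scope <- match.arg(scope)
  games <- eval_split(season, split, min_games)
  sm <- season$summaries
  key_g <- paste(games$player_id, games$session_id)
  key_s <- paste(sm$player_id, sm$session_id)
  X <- as.matrix(sm[match(key_g, key_s),
                    setdiff(names(sm), c("player_id", "session_id",
                                         "date", "kind")), drop = FALSE])
  games$game_id <- games$session_id
  out <- lapply(c(intercept = "intercept", slope = "slope"), function(tg) {
    r <- ridge_task_rows(games, X, target = tg, scope = scope, k = k)
    r$target <- tg
    r
  })
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  list(rows = rows,
       mape = vapply(out, summarise_mape, 0))
}

#' Run the full prediction-task comparison
#'
#' Executes every task on the same chronological per-player 80/20 split
#' of a season's valid game profiles and scores them with MAPE
#' (per-player average by default):
#' \itemize{
#'   \item `control` - same-game commercial features (ridge);
#'   \item `ridge_mean_commercial` / `ridge_exp_commercial` - ridge on
#'     the last-`L`-session window of commercial features pooled by mean
#'     or softmax exponential weights (decay selected on a training
#'     validation tail);
#'   \item `ridge_mean_signal` / `ridge_exp_signal` - the same on the
#'     raw-signal feature catalogue (requires `simulate_season(features
#'     = TRUE)`);
#'   \item `forecast_ensemble` - per-player uni-modal ensemble
#'     (naive/drift/theta/fourtheta/fft) on the games-only coefficient
#'     series.
#' }
#' Every task scores the identical set of (player, game) test keys.
#' Paired bootstrap contrasts are computed against the forecasting
#' reference.
#'
#' @param season An `"av_season"` from [simulate_season()].
#' @param scope `"G"` or `"I"` for the ridge-based tasks.
#' @param split Chronological train fraction (default 0.8).
#' @param min_games Minimum valid game profiles per included player;
#'   default 10 so every train series supports the theta/fft families.
#' @param L Pooling window, sessions.
#' @param k Features retained by selection.
#' @param beta_grid Candidate softmax decays (per day).
#' @param B,seed Bootstrap replicates and seed for the contrasts.
#' @return Object of class `"av_experiment"`: `ranking` (task x target
#'   mean MAPE table, ranked), `rows` (all per-game predictions),
#'   `contrasts` (each task vs the forecast ensemble), `test_keys`.
#' @export
run_experiment <- function(season, scope = "G", split = 0.8, min_games = 10,
                           L = 5, k = 10, beta_grid = c(0.1, 0.3, 0.5, 1.0),
                           B = 1000, seed = 1) {
  games <- eval_split(season, split, min_games)
  games$game_id <- games$session_id
  key_g <- paste(games$player_id, games$game_id)

  task_rows <- list()

  ## -- control: same-game commercial features
  sm <- season$summaries
  Xc <- as.matrix(sm[match(key_g, paste(sm$player_id, sm$session_id)),
                     setdiff(names(sm), c("player_id", "session_id",
                                          "date", "kind")), drop = FALSE])
  for (tg in c("intercept", "slope"))
    task_rows[[paste0("control.", tg)]] <-
      ridge_task_rows(games, Xc, tg, scope, k)

  ## -- pooled past-window ridge tasks
  feature_sets <- list(commercial = season$summaries)
  if (!is.null(season$features)) feature_sets$signal <- season$features
  for (fs in names(feature_sets)) {
    ft <- feature_sets[[fs]]
    dm_mean <- build_design_matrix(ft, games, L = L, method = "mean")
    Xp <- align_design(dm_mean, games)
    for (tg in c("intercept", "slope"))
      task_rows[[paste0("ridge_mean_", fs, ".", tg)]] <-
        ridge_task_rows(games, Xp, tg, scope, k)
    X_by_beta <- lapply(setNames(beta_grid, beta_grid), function(b)
      align_design(build_design_matrix(ft, games, L = L,
                                       method = "exponential", beta = b),
                   games))
    for (tg in c("intercept", "slope")) {
      bsel <- select_beta(games, X_by_beta, tg, k)
      task_rows[[paste0("ridge_exp_", fs, ".", tg)]] <-
        ridge_task_rows(games, X_by_beta[[bsel]], tg, scope, k)
      attr(task_rows[[paste0("ridge_exp_", fs, ".", tg)]], "beta") <-
        as.numeric(bsel)
    }
  }

  ## -- per-player forecasting ensemble on the games-only series
  for (tg in c("intercept", "slope")) {
    rows <- lapply(split(seq_len(nrow(games)), games$player_id), function(idx) {
      tr <- idx[!games$is_test[idx]]
      te <- idx[games$is_test[idx]]
      fc <- forecast_series(games[[tg]][tr], h = length(te),
                            family = "ensemble")
      data.frame(player_id = games$player_id[te],
                 game_id = games$game_id[te],
                 y_true = games[[tg]][te], y_pred = fc,
                 stringsAsFactors = FALSE)
    })
    task_rows[[paste0("forecast_ensemble.", tg)]] <- do.call(rbind, rows)
  }

  ## comparability contract: every task scored on identical test keys
  test_keys <- sort(key_g[games$is_test])
  for (nm in names(task_rows)) {
    tk <- sort(paste(task_rows[[nm]]$player_id, task_rows[[nm]]$game_id))
    if (!identical(tk, test_keys))
      stop(sprintf("task '%s' scored a different key set", nm))
  }

  ranking <- do.call(rbind, lapply(names(task_rows), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(task = parts[1], target = parts[2],
               scope = if (parts[1] == "forecast_ensemble") "I" else scope,
               aggregation = task_aggregation(parts[1]),
               mape = summarise_mape(task_rows[[nm]]),
               stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(ranking$target, ranking$mape), ]
  rownames(ranking) <- NULL

  n_players <- length(unique(games$player_id[games$is_test]))
  contrasts <- if (n_players >= 5) {
    do.call(rbind, lapply(names(task_rows), function(nm) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      ref <- task_rows[[paste0("forecast_ensemble.", parts[2])]]
      if (parts[1] == "forecast_ensemble") return(NULL)
      bs <- paired_bootstrap_compare(task_rows[[nm]], ref, B = B, seed = seed)
      data.frame(task = parts[1], target = parts[2],
                 mean_diff = bs$mean_diff, ci_lo = bs$ci[1],
                 ci_hi = bs$ci[2], p = bs$p, stringsAsFactors = FALSE)
    }))
  } else {
    message("fewer than 5 eligible players: bootstrap contrasts skipped")
    NULL
  }
  rownames(contrasts) <- NULL

  rows <- do.call(rbind, lapply(names(task_rows), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cbind(task = parts[1], target = parts[2], task_rows[[nm]],
          stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL

  structure(list(ranking = ranking, rows = rows, contrasts = contrasts,
                 test_keys = test_keys, scope = scope, split = split,
                 min_games = min_games, L = L, k = k, seed = seed),
            class = "av_experiment")
}

task_aggregation <- function(task) {
  switch(task,
         ridge_mean_commercial = , ridge_mean_signal = "mean",
         ridge_exp_commercial = , ridge_exp_signal = "exponential",
         "none")
}

## reorder a design-matrix result onto the games table (NA-free by
## construction: eval_split already required at least one predecessor)
align_design <- function(dm, games) {
  idx <- match(paste(games$player_id, games$game_id),
               paste(dm$targets$player_id, dm$targets$game_id))
  if (anyNA(idx)) stop("design matrix is missing games")
  dm$X[idx, , drop = FALSE]
}

#' @export
print.av_experiment <- function(x, ...) {
  cat(sprintf("Prediction-task comparison (scope %s, split %.2f, %d test games)\n",
              x$scope, x$split, length(x$test_keys)))
  cat("Mean MAPE by task (per-player aggregation):\n")
  print(transform(x$ranking, mape = round(mape, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.av_experiment <- function(x, target = c("intercept", "slope"), ...) {
  target <- match.arg(target)
  r <- x$rows[x$rows$target == target, ]
  ape <- abs(r$y_true - r$y_pred) / abs(r$y_true)
  op <- par(mar = c(9, 4, 2, 1))
  on.exit(par(op))
  boxplot(ape ~ r$task, las = 2, xlab = "", ylab = "absolute % error",
          main = sprintf("Per-game errors: %s", target), ...)
  invisible(x)
}
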