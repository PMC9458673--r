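#' Ridge regression with chronological cross-validation
#'
#' Fits `y = b0 + X beta` with an L2 penalty on the standardized
#' coefficients. Features are z-scored, the target is centred, and the
#' coefficients solve `(Xs'Xs + lambda I) beta = Xs' y_c`; the intercept
#' is unpenalized. When `lambda` is not supplied it is selected by
#' chronological (forward-chaining) K-fold cross-validation over a log
#' grid `10^(-3..3)`: rows are kept in date order, the validation block
#' is always later than every training row, and the mean validation MSE
#' decides.
#'
#' Constant features are dropped with a warning. With fewer rows than
#' folds the selection falls back to leave-one-out (still chronological).
#'
#' @param X Numeric matrix or data frame (named columns), n x d.
#' @param y Numeric target, length n.
#' @param lambda Penalty >= 0, or `NULL` to cross-validate.
#' @param dates Optional vector ordering the rows in time (defaults to
#'   the given row order).
#' @param nfolds Cross-validation folds (default 5).
#' @param lambda_grid Candidate penalties for selection.
#' @return Object of class `"av_ridge"` with the standardized
#'   coefficients, the chosen `lambda`, and the centring/scaling
#'   parameters needed by `predict`.
#' @examples
#' X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))
#' y <- X[, 1] - 2 * X[, 3] + rnorm(20, 0, 0.1)
#' fit <- fit_ridge(X, y, lambda = 0.1)
#' predict(fit, X)[1:3]
#' @export
fit_ridge <- function(X, y, lambda = NULL, dates = NULL, nfolds = 5,
                      lambda_grid = 10^seq(-3, 3, length.out = 13)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 2 || ncol(X) < 1) stop("need n >= 2 rows and d >= 1 features")
  if (length(y) != n) stop("'y' length must match rows of X")
  if (!is.null(dates)) {
    o <- order(dates)
    X <- X[o, , drop = FALSE]
    y <- y[o]
  }
  sds <- apply(X, 2, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
    if (!ncol(X)) stop("no non-constant features left")
  }
  mus <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mus), 2, sds, "/")
  my <- mean(y)
  yc <- y - my

  solve_ridge <- function(Xs, yc, lam) {
    d <- ncol(Xs)
    solve(crossprod(Xs) + diag(lam, d), crossprod(Xs, yc))
  }

  if (is.null(lambda)) {
    if (n < nfolds) nfolds <- n  # leave-one-out fallback
    ## forward-chaining blocks: validate each later block against all
    ## earlier rows
    fold <- cut(seq_len(n), breaks = nfolds, labels = FALSE)
    cv <- vapply(lambda_grid, function(lam) {
      errs <- c()
      for (k in 2:nfolds) {
        tr <- which(fold < k)
        va <- which(fold == k)
        if (length(tr) < 2) next
        Xtr <- Xs[tr, , drop = FALSE]
        b <- solve_ridge(Xtr, yc[tr] - mean(yc[tr]), lam)
        pred <- Xs[va, , drop = FALSE] %*% b + mean(yc[tr]) + my
        errs <- c(errs, (y[va] - pred)^2)
      }
      mean(errs)
    }, 0)
    lambda <- lambda_grid[which.min(cv)]
  }
  beta <- solve_ridge(Xs, yc, lambda)
  structure(list(coef = setNames(as.numeric(beta), colnames(X)),
                 intercept = my, lambda = lambda,
                 feature_means = mus, feature_sds = sds,
                 features = colnames(X), n = n),
            class = "av_ridge")
}

#' @export
coef.av_ridge <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coef)
}

#' @export
print.av_ridge <- function(x, ...) {
  cat(sprintf("Ridge fit: %d features, n = %d, lambda = %g\n",
              length(x$coef), x$n, x$lambda))
  print(round(coef(x), 4))
  invisible(x)
}

#' Predict from a ridge fit
#'
#' Standardizes new rows with the stored training means and scales,
#' applies the coefficients and adds the intercept. The feature set must
#' match the fit.
#'
#' @param object An `"av_ridge"` fit.
#' @param newdata Matrix or data frame with the fit's feature columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.av_ridge <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$features))
      stop("newdata has a different number of features than the fit")
    colnames(newdata) <- object$features
  }
  if (!all(object$features %in% colnames(newdata)))
    stop("newdata is missing features: ",
         paste(setdiff(object$features, colnames(newdata)), collapse = ", "))
  Xs <- sweep(sweep(newdata[, object$features, drop = FALSE], 2,
                    object$feature_means), 2, object$feature_sds, "/")
  as.numeric(Xs %*% object$coef + object$intercept)
}
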