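#' Subject-level train/test split
#'
#' All steps of a subject fall on one side of the split. The default test
#' fraction 7/43 reproduces a 36/7 split on a 43-subject cohort.
#'
#' @param subject_ids Character vector of unique subject ids (>= 2).
#' @param test_fraction Fraction of subjects assigned to the test set.
#' @param seed Integer seed (its own sub-stream, so the split is stable).
#' @return List with `train` and `test` character vectors (disjoint).
#' @export
split_subjects <- function(subject_ids, test_fraction = 7 / 43, seed = 1L) {
  ids <- unique(subject_ids)
  if (length(ids) < 2L) stop("need at least 2 subjects to split", call. = FALSE)
  n_test <- max(1L, round(length(ids) * test_fraction))
  set.seed(sub_seed(seed, "split"))
  test <- sort(sample(ids, n_test))
  list(train = setdiff(ids, test), test = test)
}

#' Default regularization grid
#'
#' 20 log-spaced penalty values spanning \[5e-6, 0.05\].
#'
#' @param n Number of grid points.
#' @param lambda_min,lambda_max Grid bounds.
#' @return Increasing numeric vector.
#' @export
lambda_grid <- function(n = 20L, lambda_min = 5e-6, lambda_max = 0.05) {
  exp(seq(log(lambda_min), log(lambda_max), length.out = n))
}

#' Lasso objective value
#'
#' \eqn{(1/2n) \sum_i (y_i - \beta_0 - x_i \beta)^2 + \lambda \|\beta\|_1}
#' (intercept unpenalized).
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param intercept Intercept.
#' @param beta Coefficient vector.
#' @param lambda Penalty.
#' @return Objective value.
#' @export
lasso_objective <- function(X, y, intercept, beta, lambda) {
  r <- y - intercept - as.numeric(as.matrix(X) %*% beta)
  sum(r^2) / (2 * length(y)) + lambda * sum(abs(beta))
}

#' Fit a Lasso regression
#'
#' Minimizes \eqn{(1/2n)\sum_i (y_i - \beta_0 - x_i\beta)^2 +
#' \lambda\|\beta\|_1} with an unpenalized intercept, by cyclic coordinate
#' descent in covariance form. Deterministic for fixed inputs; see `tol` for
#' the convergence rule.
#'
#' @param X Numeric design matrix (typically standardized features).
#' @param y Numeric response.
#' @param lambda Penalty (>= 0).
#' @param tol Convergence tolerance: a sweep ends iteration when the largest
#'   variance-scaled squared coefficient update `d_j (delta beta_j)^2` falls
#'   below `tol` (default 1e-7).
#' @param max_iter Maximum coordinate-descent sweeps.
#' @param beta_init Optional warm-start coefficients.
#' @return A `lasso_fit` with `intercept`, `coefficients`, `lambda`.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-7, max_iter = 10000L,
                      beta_init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    stop("X and y must be finite", call. = FALSE)
  }
  p <- ncol(X)
  mx <- colMeans(X)
  my <- mean(y)
  Xc <- sweep(X, 2L, mx)
  yc <- y - my
  C <- crossprod(Xc) / n
  b <- as.numeric(crossprod(Xc, yc)) / n
  d <- diag(C)
  beta0 <- if (!is.null(beta_init)) as.numeric(beta_init) else numeric(p)
  sol <- cd_lasso(C, b, d, lambda, beta0 + 0, tol, as.integer(max_iter))
  beta <- as.numeric(sol$beta)
  names(beta) <- colnames(X)
  structure(list(intercept = my - sum(mx * beta),
                 coefficients = beta, lambda = lambda, sweeps = sol$sweeps),
            class = "lasso_fit")
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  object$intercept + as.numeric(X %*% object$coefficients)
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<lasso_fit> lambda = %.3g, %d/%d nonzero coefficients, intercept = %.4g\n",
              x$lambda, nz, length(x$coefficients), x$intercept))
  invisible(x)
}

# warm-started path over a decreasing-lambda sequence; returns list of fits
# in the original (increasing) order
fit_lasso_path <- function(X, y, lambdas, tol = 1e-7) {
  ord <- order(lambdas, decreasing = TRUE)
  fits <- vector("list", length(lambdas))
  beta <- NULL
  for (k in ord) {
    fit <- fit_lasso(X, y, lambdas[k], tol = tol, beta_init = beta)
    beta <- fit$coefficients
    fits[[k]] <- fit
  }
  fits
}

#' Mean-regressor baseline
#'
#' Always predicts the training-set mean of the target.
#'
#' @param y_train Training target values.
#' @return A `mean_regressor` object with a `predict` method.
#' @export
mean_regressor <- function(y_train) {
  structure(list(mean = mean(y_train)), class = "mean_regressor")
}

#' @export
predict.mean_regressor <- function(object, newdata, ...) {
  n <- if (is.data.frame(newdata) || is.matrix(newdata)) nrow(newdata) else length(newdata)
  rep(object$mean, n)
}

#' Regression metrics
#'
#' RMSE, MAPE (in percent) and the determination coefficient, with R^2
#' computed against the evaluation split's own mean (so a constant predictor
#' can score negative R^2 on a shifted test set).
#'
#' @param pred Predicted values.
#' @param truth Observed values (nonzero, finite; equal length).
#' @return Data frame with `rmse`, `mape_percent`, `r2`, `n_steps`.
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), all(is.finite(pred)), all(is.finite(truth)))
  if (any(truth == 0)) stop("MAPE undefined: truth contains zeros", call. = FALSE)
  err <- pred - truth
  ss_tot <- sum((truth - mean(truth))^2)
  data.frame(rmse = sqrt(mean(err^2)),
             mape_percent = 100 * mean(abs(err) / abs(truth)),
             r2 = 1 - sum(err^2) / ss_tot,
             n_steps = length(truth))
}

#' Metrics per speed group
#'
#' @param pred,truth Equal-length vectors.
#' @param speeds Per-step speeds.
#' @param groups Speed groups to evaluate (default: the distinct speeds).
#' @return Data frame with one row per non-empty group plus the metric
#'   columns; empty groups are omitted with a warning.
#' @export
evaluate_by_speed <- function(pred, truth, speeds, groups = NULL) {
  if (is.null(groups)) groups <- sort(unique(speeds))
  rows <- list()
  for (g in groups) {
    sel <- speeds == g
    if (!any(sel)) {
      warning(sprintf("speed group %g is empty; omitted", g), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- cbind(speed = g, evaluate_predictions(pred[sel], truth[sel]))
  }
  do.call(rbind, rows)
}

#' Leave-one-subject-out cross-validation for the penalty
#'
#' For each penalty in the grid, each training subject is held out in turn:
#' the scaler is fitted on the remaining subjects only, the Lasso is fitted on
#' their standardized rows (warm-started along the path), and the held-out
#' subject's steps are predicted. The validation score per penalty is the
#' unweighted mean over folds of the per-fold RMSE; the selected penalty
#' minimizes it, with ties broken toward stronger regularization.
#'
#' @param features Cleaned (unstandardized) feature table with key columns.
#' @param y Target vector aligned with `features` rows.
#' @param lambdas Penalty grid (default [lambda_grid()]).
#' @param tol Coordinate-descent tolerance.
#' @return List: `selected_lambda`, `scores` (data frame `lambda`,
#'   `mean_rmse`), `fold_rmse` (subjects x lambdas matrix).
#' @export
loso_cv <- function(features, y, lambdas = lambda_grid(), tol = 1e-7) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L) stop("need at least 2 training subjects", call. = FALSE)
  keys <- intersect(feature_key_cols, names(features))
  fold_rmse <- matrix(NA_real_, nrow = length(subjects), ncol = length(lambdas),
                      dimnames = list(subjects, NULL))
  for (s in subjects) {
    hold <- features$subject_id == s
    train <- features[!hold, , drop = FALSE]
    test <- features[hold, , drop = FALSE]
    scaler <- fit_scaler(train)
    tr <- apply_scaler(train, scaler)
    te <- apply_scaler(test, scaler)
    feat_cols <- setdiff(names(tr), keys)
    Xtr <- as.matrix(tr[, feat_cols, drop = FALSE])
    Xte <- as.matrix(te[, feat_cols, drop = FALSE])
    fits <- fit_lasso_path(Xtr, y[!hold], lambdas, tol = tol)
    for (k in seq_along(lambdas)) {
      pred <- fits[[k]]$intercept + as.numeric(Xte %*% fits[[k]]$coefficients)
      fold_rmse[s, k] <- sqrt(mean((pred - y[hold])^2))
    }
  }
  mean_rmse <- colMeans(fold_rmse)
  best <- max(which(mean_rmse <= min(mean_rmse) + 1e-12))
  list(selected_lambda = lambdas[best],
       scores = data.frame(lambda = lambdas, mean_rmse = mean_rmse),
       fold_rmse = fold_rmse)
}

#' Train a Lasso model on a full training table
#'
#' Fits the scaler on all training rows, standardizes, and fits the Lasso at
#' the given penalty. The returned model carries its scaler so prediction on
#' new (unstandardized) tables applies the training transform.
#'
#' @param features Cleaned training feature table.
#' @param y Training target vector.
#' @param lambda Penalty (typically from [loso_cv()]).
#' @param tol Coordinate-descent tolerance.
#' @return A `vgrf_model`.
#' @export
train_lasso_model <- function(features, y, lambda, tol = 1e-7) {
  keys <- intersect(feature_key_cols, names(features))
  scaler <- fit_scaler(features)
  tr <- apply_scaler(features, scaler)
  feat_cols <- setdiff(names(tr), keys)
  fit <- fit_lasso(as.matrix(tr[, feat_cols, drop = FALSE]), y, lambda, tol = tol)
  structure(list(fit = fit, scaler = scaler, feature_cols = feat_cols,
                 lambda = lambda, train_subjects = unique(features$subject_id)),
            class = "vgrf_model")
}

#' @export
predict.vgrf_model <- function(object, newdata, ...) {
  td <- apply_scaler(newdata, object$scaler)
  X <- as.matrix(td[, object$feature_cols, drop = FALSE])
  object$fit$intercept + as.numeric(X %*% object$fit$coefficients)
}
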