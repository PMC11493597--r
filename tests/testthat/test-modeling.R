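# brute-force minimization of the lasso objective, independent of the
# coordinate-descent implementation: Nelder-Mead restarts on the convex
# objective over (intercept, beta)
brute_force_lasso <- function(X, y, lambda) {
  obj <- function(par) lasso_objective(X, y, par[1], par[-1], lambda)
  p <- ncol(X)
  best <- NULL
  for (start in list(rep(0, p + 1), c(mean(y), rep(0.5, p)), c(mean(y), rep(-0.5, p)))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(intercept = best$par[1], beta = best$par[-1], value = best$value)
}

std_pop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

test_that("subject-level splits are disjoint, sized and reproducible", {
  ids <- sprintf("S%02d", 1:43)
  sp <- split_subjects(ids, seed = 3)
  expect_length(sp$train, 36)
  expect_length(sp$test, 7)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_subjects(ids, seed = 3))
  expect_false(identical(sp$test, split_subjects(ids, seed = 4)$test))
  expect_error(split_subjects("only_one"), "2 subjects")
})

test_that("lasso reproduces the soft-thresholding closed form", {
  set.seed(5)
  n <- 40
  x <- std_pop(stats::rnorm(n))          # orthonormal design: x'x/n = 1
  y <- 1.5 + 0.8 * x + stats::rnorm(n, 0, 0.3)
  b_ols <- mean(x * (y - mean(y)))       # OLS slope under x'x/n = 1
  for (lam in c(0.01, 0.2, 1.5)) {
    fit <- fit_lasso(matrix(x, ncol = 1), y, lam)
    expected <- sign(b_ols) * max(abs(b_ols) - lam, 0)
    expect_equal(unname(fit$coefficients), expected, tolerance = 1e-6)
  }
})

test_that("strong penalties with weak features reduce to the mean regressor", {
  set.seed(6)
  n <- 60
  X <- matrix(stats::rnorm(2 * n, 0, 1e-3), ncol = 2)  # uninformative
  y <- stats::rnorm(n, 5, 0.1)
  fit <- fit_lasso(X, y, 0.05)
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(fit$intercept, mean(y))
})

test_that("lasso at zero penalty interpolates two points exactly", {
  X <- matrix(c(0, 1), ncol = 1)
  y <- c(3, 7)
  fit <- fit_lasso(X, y, 0)
  expect_equal(unname(fit$coefficients), 4, tolerance = 1e-8)
  expect_equal(fit$intercept, 3, tolerance = 1e-8)
})

test_that("lasso agrees with a brute-force objective minimization", {
  set.seed(7)
  n <- 20
  for (p in 1:3) {
    X <- matrix(stats::rnorm(n * p), ncol = p)
    X <- apply(X, 2, std_pop)
    beta <- c(1.2, -0.7, 0.3)[1:p]
    y <- 2 + X %*% beta + stats::rnorm(n, 0, 0.2)
    for (lam in c(0.02, 0.3)) {
      fit <- fit_lasso(X, y, lam)
      bf <- brute_force_lasso(X, y, lam)
      expect_equal(unname(fit$coefficients), bf$beta, tolerance = 1e-4)
      expect_lte(lasso_objective(X, y, fit$intercept, fit$coefficients, lam),
                 bf$value + 1e-8)
    }
  }
})

test_that("the coefficient l1-norm is non-increasing along the penalty grid", {
  set.seed(8)
  n <- 50
  X <- apply(matrix(stats::rnorm(n * 5), ncol = 5), 2, std_pop)
  y <- 1 + X %*% c(0.9, -0.5, 0.3, 0, 0) + stats::rnorm(n, 0, 0.3)
  grid <- lambda_grid()
  norms <- vapply(grid, function(l) sum(abs(fit_lasso(X, y, l)$coefficients)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("lasso matches an independent reference implementation", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  n <- 80
  X <- apply(matrix(stats::rnorm(n * 4), ncol = 4), 2, std_pop)
  y <- 0.5 + X %*% c(1, -0.4, 0, 0.2) + stats::rnorm(n, 0, 0.3)
  for (lam in c(0.01, 0.1)) {
    fit <- fit_lasso(X, y, lam, tol = 1e-12)
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(fit$coefficients), as.numeric(g$beta), tolerance = 1e-4)
    expect_equal(fit$intercept, as.numeric(g$a0), tolerance = 1e-4)
  }
})

test_that("mean regressor predicts the training mean and can score negative R2", {
  mr <- mean_regressor(c(1, 2, 3))
  expect_equal(predict(mr, data.frame(x = 1:5)), rep(2, 5))
  expect_equal(mean_regressor(7)$mean, 7)

  # shifted test distribution: constant prediction scores below zero
  y_test <- c(5, 6, 7)
  ev <- evaluate_predictions(predict(mr, data.frame(x = 1:3)), y_test)
  expect_lt(ev$r2, 0)
})

test_that("metrics reproduce hand-computed examples", {
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mape_percent, 0)
  expect_equal(perfect$r2, 1)

  ev <- evaluate_predictions(c(1, 5), c(2, 4))
  expect_equal(ev$mape_percent, 37.5)
  expect_equal(ev$rmse, 1)

  y <- c(2, 4, 9)
  ev2 <- evaluate_predictions(rep(mean(y), 3), y)
  expect_equal(ev2$r2, 0)

  expect_error(evaluate_predictions(c(1, 2), c(0, 1)), "zeros")
})

test_that("per-speed MSEs recombine to the overall MSE (step-weighted)", {
  set.seed(10)
  speeds <- rep(c(2.22, 2.5, 2.78), times = c(10, 15, 5))
  truth <- stats::rnorm(30, 2.4, 0.2)
  pred <- truth + stats::rnorm(30, 0, 0.1)
  overall <- evaluate_predictions(pred, truth)
  by_sp <- evaluate_by_speed(pred, truth, speeds)
  expect_equal(sum(by_sp$n_steps * by_sp$rmse^2), 30 * overall$rmse^2)
  expect_warning(evaluate_by_speed(pred, truth, speeds, groups = c(2.22, 3.33)),
                 "empty")
})

test_that("LOSO-CV scores every subject fold and prefers stronger ties", {
  set.seed(12)
  n_per <- 8
  ids <- rep(sprintf("S%d", 1:5), each = n_per)
  tbl <- data.frame(subject_id = ids, speed = 2.78,
                    step_index = sequence(rep(n_per, 5)),
                    x1 = stats::rnorm(40), x2 = stats::rnorm(40),
                    stringsAsFactors = FALSE)

  # constant target: every penalty gives zero validation error and the
  # tie-break selects the strongest penalty
  cv0 <- loso_cv(tbl, rep(3.3, 40))
  expect_equal(dim(cv0$fold_rmse), c(5, 20))
  expect_equal(max(cv0$scores$mean_rmse), 0)
  expect_equal(cv0$selected_lambda, max(lambda_grid()))

  # informative linear target: the selected model beats the mean regressor
  y <- 1 + 0.8 * tbl$x1 + stats::rnorm(40, 0, 0.05)
  cv <- loso_cv(tbl, y)
  mr_score <- mean(vapply(unique(ids), function(s) {
    hold <- ids == s
    sqrt(mean((mean(y[!hold]) - y[hold])^2))
  }, numeric(1)))
  expect_lt(min(cv$scores$mean_rmse), mr_score)
})

test_that("held-out subjects never influence fold scalers or fits", {
  set.seed(13)
  ids <- rep(sprintf("S%d", 1:4), each = 10)
  tbl <- data.frame(subject_id = ids, speed = 2.78, step_index = sequence(rep(10, 4)),
                    x1 = stats::rnorm(40), x2 = stats::rnorm(40),
                    stringsAsFactors = FALSE)
  y <- 2 + tbl$x1 - 0.5 * tbl$x2 + stats::rnorm(40, 0, 0.1)

  cv <- loso_cv(tbl, y, lambdas = c(0.001, 0.01))

  # recompute the S1 fold by hand: scaler and fit from the other subjects only
  hold <- ids == "S1"
  sc <- fit_scaler(tbl[!hold, ])
  tr <- apply_scaler(tbl[!hold, ], sc)
  te <- apply_scaler(tbl[hold, ], sc)
  for (k in 1:2) {
    fit <- fit_lasso(as.matrix(tr[, c("x1", "x2")]), y[!hold], c(0.001, 0.01)[k])
    pred <- fit$intercept + as.matrix(te[, c("x1", "x2")]) %*% fit$coefficients
    expect_equal(unname(cv$fold_rmse["S1", k]), sqrt(mean((pred - y[hold])^2)),
                 tolerance = 1e-6)
  }

  # perturbing the held-out subject's feature rows leaves the other folds'
  # scores untouched (their training sets do not contain S1's rows only when
  # S1 is held out; here we perturb a subject entirely out of the train data)
  tbl2 <- tbl
  tbl2[hold, c("x1", "x2")] <- tbl2[hold, c("x1", "x2")] * 100
  cv2 <- loso_cv(tbl2, y, lambdas = c(0.001, 0.01))
  # the S1 fold's *model* is unchanged; only its evaluation rows moved, so
  # other subjects' folds (which include perturbed S1 in training) may change,
  # but the S1 fold trained without S1 yields the same fitted coefficients
  sc2 <- fit_scaler(tbl2[!hold, ])
  expect_identical(sc$center, sc2$center)
  expect_identical(sc$scale, sc2$scale)
})

test_that("lasso recovers a linear signal and approaches the noise floor", {
  set.seed(14)
  n <- 400
  ids <- rep(sprintf("S%d", 1:10), each = 40)
  X <- matrix(stats::rnorm(n * 3), ncol = 3)
  beta <- c(1.0, -0.6, 0.4)
  sd_noise <- 0.1
  y <- 2 + X %*% beta + stats::rnorm(n, 0, sd_noise)

  fit <- fit_lasso(apply(X, 2, std_pop), y, 1e-4)
  # coefficients on the standardized scale: beta_j * sd_j
  sds <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(unname(fit$coefficients), beta * sds, tolerance = 0.1)

  tr <- ids %in% sprintf("S%d", 1:8)
  fit2 <- fit_lasso(X[tr, ], y[tr], 1e-4)
  pred <- fit2$intercept + X[!tr, ] %*% fit2$coefficients
  rmse <- sqrt(mean((pred - y[!tr])^2))
  expect_lt(rmse, 1.2 * sd_noise)
})
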