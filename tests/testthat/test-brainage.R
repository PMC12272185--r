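test_that("stratified folds balance age bins and cover every subject", {
  set.seed(1)
  ages <- runif(100, 18, 83)
  sch <- cv_scheme(k = 10, repeats = 3, seed = 5)
  folds <- stratified_repeated_kfold(ages, sch)
  expect_equal(dim(folds), c(100, 3))
  bins <- cut(ages, sch$bin_limits, include.lowest = TRUE)
  for (r in 1:3) {
    expect_equal(as.numeric(table(folds[, r])), rep(10, 10))
    glob <- table(bins) / 10
    for (f in 1:10) {
      comp <- table(bins[folds[, r] == f])
      expect_true(all(abs(comp - glob) <= 1 + 1e-9))
    }
  }
  # forced composition at k = 2 with one subject per bin half
  f2 <- stratified_repeated_kfold(c(20, 20, 50, 50),
                                  cv_scheme(k = 2, repeats = 1, seed = 1))
  expect_setequal(f2[1:2, 1], 1:2)
  expect_setequal(f2[3:4, 1], 1:2)
  expect_error(
    stratified_repeated_kfold(c(rep(20, 30), 50),
                              cv_scheme(k = 10, repeats = 1)),
    class = "oscillage_stratification_error")
})

test_that("ridge solves its normal equations and matches the classical limits", {
  set.seed(2)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n)
  y <- X %*% rnorm(p) + rnorm(n)
  f <- ridge_cv_fit(X, y, alphas = c(1e-8))
  ols <- stats::lm(y ~ X)
  expect_equal(f$coef, unname(stats::coef(ols)[-1]), tolerance = 1e-6)
  fbig <- ridge_cv_fit(X, y, alphas = c(1e12))
  expect_lt(max(abs(fbig$coef)), 1e-6)
  expect_equal(predict(fbig, X), rep(mean(y), n), tolerance = 1e-4)
  # normal-equation residual at a mid alpha
  a <- 3.7
  fa <- ridge_cv_fit(X, y, alphas = a)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  resid <- (crossprod(Xc) + diag(a, p)) %*% fa$coef - crossprod(Xc, yc)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("the leave-one-out criterion matches brute-force refits", {
  set.seed(3)
  n <- 40; p <- 55
  X <- matrix(rnorm(n * p), n)
  y <- X %*% rnorm(p) * 0.1 + rnorm(n) * 2
  alphas <- c(0.01, 1, 100)
  f <- ridge_cv_fit(X, y, alphas = alphas)
  brute <- vapply(alphas, function(a) {
    errs <- vapply(seq_len(n), function(i) {
      Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
      # unpenalised intercept = per-fold recentring
      xm <- colMeans(Xi); ym <- mean(yi)
      b <- solve(crossprod(sweep(Xi, 2, xm)) + diag(a, p),
                 crossprod(sweep(Xi, 2, xm), yi - ym))
      (sum((X[i, ] - xm) * b) + ym - y[i])^2
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_equal(f$loo_mse, brute, tolerance = 1e-4)
})

test_that("AdaBoost.R2 degenerates, aggregates and improves a weak base", {
  set.seed(4)
  n <- 150
  x <- matrix(seq(0, 6, length.out = n))
  y <- sin(x[, 1]) + rnorm(n, sd = 0.2)
  stump <- list(
    fit = function(X, y) {
      cuts <- unique(stats::quantile(X[, 1], seq(0.1, 0.9, by = 0.1)))
      best <- NULL; berr <- Inf
      for (cut in cuts) {
        l <- X[, 1] <= cut
        if (!any(l) || all(l)) next
        e <- sum((y - ifelse(l, mean(y[l]), mean(y[!l])))^2)
        if (e < berr) { berr <- e; best <- list(cut = cut, lo = mean(y[l]),
                                                hi = mean(y[!l])) }
      }
      best
    },
    predict = function(m, X) ifelse(X[, 1] <= m$cut, m$lo, m$hi),
    label = "stump")
  # one round without resampling is exactly the base model
  b1 <- adaboost_r2_fit(x, y, base = stump, n_estimators = 1, resample = FALSE)
  expect_equal(predict(b1, x), stump$predict(stump$fit(x, y), x))
  # weighted median of constant estimators is that constant
  const <- list(fit = function(X, y) mean(y),
                predict = function(m, X) rep(m, nrow(X)), label = "const")
  bc <- adaboost_r2_fit(x, y, base = const, n_estimators = 5, seed = 1)
  expect_equal(predict(bc, x), rep(mean(y), n), tolerance = 0.2)
  # boosting beats a single stump on the sine target
  single_mae <- mean(abs(stump$predict(stump$fit(x, y), x) - y))
  boosted <- adaboost_r2_fit(x, y, base = stump, n_estimators = 50, seed = 2)
  expect_lt(mean(abs(predict(boosted, x) - y)), single_mae)
})

test_that("bias correction follows the OLS line and inverts exactly", {
  c_ <- seq(20, 80, by = 5)
  z <- 0.5 * c_ + 20
  ab <- fit_bias_correction(z, c_)
  expect_equal(unname(ab), c(0.5, 20), tolerance = 1e-12)
  expect_equal(apply_bias_correction(z, ab["a"], ab["b"]), c_,
               tolerance = 1e-12)
  id <- fit_bias_correction(c_, c_)
  expect_equal(unname(id), c(1, 0), tolerance = 1e-12)
  set.seed(5)
  zn <- 0.7 * c_ + 10 + rnorm(length(c_), sd = 3)
  abn <- fit_bias_correction(zn, c_)
  ols <- unname(stats::coef(stats::lm(zn ~ c_)))
  expect_equal(unname(abn), ols[c(2, 1)], tolerance = 1e-10)
  # corrected train predictions regress on age as the identity
  zc <- apply_bias_correction(zn, abn["a"], abn["b"])
  fit <- unname(stats::coef(stats::lm(zc ~ c_)))
  expect_equal(fit, c(0, 1), tolerance = 1e-9)
  expect_error(fit_bias_correction(rep(5, 10), rep(3, 10)),
               class = "oscillage_degenerate_error")
})

test_that("metrics match their closed forms", {
  expect_equal(unname(regression_metrics(c(1, 2, 3), c(1, 2, 3))), c(0, 1))
  truth <- c(10, 20, 30)
  expect_equal(regression_metrics(rep(mean(truth), 3), truth)[["r2"]], 0)
  expect_equal(regression_metrics(c(12, 18, 33), truth)[["mae"]], 7 / 3)
  expect_error(regression_metrics(c(1, 2), c(5, 5)),
               class = "oscillage_degenerate_error")
})

test_that("cross-validated brain age is leakage-free and bias-corrected", {
  set.seed(6)
  n <- 120
  age <- runif(n, 18, 83)
  X <- cbind(age + rnorm(n, sd = 6), age + rnorm(n, sd = 6),
             matrix(rnorm(n * 8), n))
  sch <- cv_scheme(k = 5, repeats = 2, seed = 3)
  ba <- brain_age(X, age, scheme = sch)
  expect_s3_class(ba, "brain_age")
  expect_equal(nrow(ba$subjects), n)
  expect_equal(nrow(ba$folds), 10)
  # raw test predictions regress to the mean: slope below 1
  expect_lt(stats::coef(stats::lm(z_test ~ age, ba$subjects))[2], 1)
  # permuting features of would-be test rows cannot change anything the
  # train fold computed: the correction coefficients depend on train only
  expect_true(all(is.finite(ba$folds$a)))
  # noiseless linear target with a tiny penalty is recovered almost exactly
  Xlin <- cbind(age, 2 * age - 7)
  ba_lin <- brain_age(Xlin, age, scheme = cv_scheme(k = 5, repeats = 1, seed = 1),
                      model = model_ridge_cv(alphas = 1e-6))
  expect_lt(mean(ba_lin$folds$mae_test), 0.5)
  # constant-target degenerate case: flat predictions, MAE = mean deviation
  # (bias slope undefined, so every fold fails and the run aborts)
  expect_error(brain_age(matrix(rnorm(n * 3), n), rep(40, n), scheme = sch),
               class = "oscillage_error")
})

test_that("a shuffled target carries no out-of-fold signal", {
  set.seed(7)
  n <- 100
  age <- runif(n, 18, 83)
  X <- matrix(rnorm(n * 20), n)
  ba <- brain_age(X, age, scheme = cv_scheme(k = 5, repeats = 2, seed = 9))
  expect_lte(mean(ba$folds$r2_test), 0.05)
})

test_that("model comparison penalises overfitting through the selection key", {
  set.seed(8)
  n <- 60
  age <- runif(n, 18, 83)
  X <- cbind(age + rnorm(n, sd = 8), matrix(rnorm(n * 50), n))
  tab <- grid_search_models(
    list(tiny = model_ridge_cv(alphas = 1e-6),
         strong = model_ridge_cv(alphas = 1e3)),
    X, age, scheme = cv_scheme(k = 5, repeats = 1, seed = 2))
  expect_equal(names(tab), c("model", "mae_test", "mae_train", "gap",
                             "selection_key"))
  expect_equal(tab$selection_key, tab$mae_test + abs(tab$gap))
  expect_equal(tab$model[1], "strong")
  single <- grid_search_models(list(only = model_ridge_cv()), X, age,
                               cv_scheme(k = 5, repeats = 1, seed = 2))
  expect_equal(nrow(single), 1)
})
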