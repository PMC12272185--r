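#' Cross-validation scheme for brain-age modelling
#'
#' Repeated stratified K-fold over a continuous response binned into
#' linearly spaced age groups, so every fold carries a representative age
#' distribution even when parts of the range are sparsely sampled.
#'
#' @param k folds (default 10).
#' @param repeats repetitions (default 10).
#' @param bin_limits ascending stratification limits in years
#'   (default 0, 22.5, 45, 67.5, 90).
#' @param seed integer seed; repeat r reshuffles with `seed + r`.
#' @return Object of class `cv_scheme`.
#' @export
cv_scheme <- function(k = 10L, repeats = 10L,
                      bin_limits = c(0, 22.5, 45, 67.5, 90), seed = 1L) {
  if (k < 2L) abort_config("k must be at least 2")
  if (is.unsorted(bin_limits, strictly = TRUE))
    abort_config("bin_limits must be strictly ascending")
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 bin_limits = bin_limits, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Stratified repeated K-fold assignments
#'
#' Within each repeat, subjects are shuffled within their age bin and dealt
#' round-robin to folds, so per-fold bin composition deviates from the
#' global composition by at most one subject per bin. An occupied bin with a
#' single subject cannot be stratified and raises an error naming it; bins
#' with fewer subjects than folds are allowed (some folds simply go without)
#' so that modest uniform lifespan cohorts remain valid.
#'
#' @param ages numeric vector, years.
#' @param scheme a [cv_scheme()].
#' @return Integer matrix, subjects x repeats, entries in `1..k` giving each
#'   subject's test fold per repeat.
#' @export
stratified_repeated_kfold <- function(ages, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  bins <- cut(ages, scheme$bin_limits, include.lowest = TRUE)
  if (anyNA(bins)) abort_config("ages outside the stratification limits")
  counts <- table(bins)
  sparse <- counts > 0 & counts < 2
  if (any(sparse))
    abort("stratification bins too sparse for k folds: " %+%
            paste(names(counts)[sparse], collapse = ", "),
          "oscillage_stratification_error")
  out <- matrix(0L, length(ages), scheme$repeats)
  for (r in seq_len(scheme$repeats)) {
    with_seed(scheme$seed + r, {
      fold <- integer(length(ages))
      offset <- 0L
      for (b in levels(bins)) {
        idx <- which(bins == b)
        if (!length(idx)) next
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% scheme$k) + 1L
        offset <- offset + length(idx)
      }
      out[, r] <- fold
    })
  }
  out
}

`%+%` <- function(a, b) paste0(a, b)

# ---- Models ----------------------------------------------------------------

#' Ridge regression with efficient leave-one-out penalty selection
#'
#' Closed-form ridge solutions over a penalty grid via the SVD of the
#' (centred) design; the penalty is chosen by the exact leave-one-out mean
#' squared error computed from the hat-matrix diagonal, without refitting.
#' Deterministic.
#'
#' @param X numeric design matrix (rows = subjects).
#' @param y numeric response.
#' @param alphas positive penalty grid (default 13 points log-spaced
#'   1e-3..1e5, admitting very strong regularisation).
#' @return Object of class `ridge_cv_fit` with `coef`, `intercept`, `alpha`,
#'   `loo_mse` (per grid point).
#' @export
ridge_cv_fit <- function(X, y, alphas = 10^seq(-3, 5, length.out = 13)) {
  if (any(alphas <= 0)) abort_config("alphas must be positive")
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  d <- sv$d
  Uty <- crossprod(sv$u, yc)
  # residual off the column space (exactly zero when p >= n)
  r_perp <- yc - sv$u %*% Uty
  u2 <- sv$u^2
  row_u2 <- rowSums(u2)
  n_tr <- nrow(Xc)
  loo <- vapply(alphas, function(a) {
    # complement form a/(d^2+a) avoids cancellation at small penalties;
    # the unpenalised intercept contributes 1/n to every hat diagonal
    s1 <- a / (d^2 + a)
    resid <- sv$u %*% (s1 * Uty) + r_perp
    one_minus_h <- rowSums(sweep(u2, 2, s1, `*`)) + pmax(0, 1 - row_u2) - 1 / n_tr
    mean((resid / pmax(one_minus_h, 1e-12))^2)
  }, numeric(1))
  a <- alphas[which.min(loo)]
  beta <- sv$v %*% ((d / (d^2 + a)) * Uty)
  structure(list(coef = as.numeric(beta), intercept = ym - sum(xm * beta),
                 alpha = a, alphas = alphas, loo_mse = loo),
            class = "ridge_cv_fit")
}

#' @export
predict.ridge_cv_fit <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$coef + object$intercept)
}

#' AdaBoost.R2 boosted regression
#'
#' Drucker's AdaBoost.R2 with linear loss: each round fits the base model on
#' a weighted bootstrap of the training rows, weighs the round by its
#' average relative loss, updates sample weights multiplicatively, and
#' stops early when the average loss reaches 0.5. Prediction is the
#' weighted median of the rounds' predictions.
#'
#' @param X design matrix; `y` response.
#' @param y numeric response.
#' @param base list with `fit(X, y)` and `predict(model, X)` functions
#'   (e.g. [model_ridge_cv()]).
#' @param n_estimators boosting rounds (default 50).
#' @param learning_rate shrinkage of the weight updates (default 1).
#' @param seed integer seed for the weighted resampling.
#' @param resample logical; `FALSE` fits the base model on weight-ignoring
#'   full data each round (degenerates to the base model for one round).
#' @return Object of class `adaboost_r2` with `models`, `betas`.
#' @export
adaboost_r2_fit <- function(X, y, base = model_ridge_cv(), n_estimators = 50,
                            learning_rate = 1, seed = 1L, resample = TRUE) {
  if (n_estimators < 1) abort_config("n_estimators must be at least 1")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  models <- list(); betas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      fit <- tryCatch({
        if (resample) {
          idx <- sample.int(n, n, replace = TRUE, prob = w)
          base$fit(X[idx, , drop = FALSE], y[idx])
        } else base$fit(X, y)
      }, error = function(e)
        abort("base model failed in boosting round " %+% m %+% ": " %+%
                conditionMessage(e), "oscillage_boosting_error"))
      pred <- base$predict(fit, X)
      err <- abs(pred - y)
      emax <- max(err)
      if (emax == 0) { models[[m]] <- fit; betas[m] <- 1e-10; break }
      l <- err / emax                       # linear loss
      lbar <- sum(w * l)
      if (lbar >= 0.5) {
        if (length(models) == 0L) { models[[1]] <- fit; betas[1] <- 1 }
        break
      }
      beta <- lbar / (1 - lbar)
      models[[m]] <- fit
      betas[m] <- beta
      w <- w * beta^((1 - l) * learning_rate)
      w <- w / sum(w)
    }
  })
  structure(list(models = models, betas = betas, base = base),
            class = "adaboost_r2")
}

# Weighted median along rows of a predictions matrix (rows = samples,
# columns = estimators), weights log(1/beta).
.weighted_median <- function(P, wts) {
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1]]
  })
}

#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  P <- vapply(object$models, function(m) object$base$predict(m, newdata),
              numeric(nrow(as.matrix(newdata))))
  P <- matrix(P, nrow = nrow(as.matrix(newdata)))
  wts <- log(1 / pmax(object$betas, 1e-300))
  if (length(object$models) == 1L) return(as.numeric(P[, 1]))
  .weighted_median(P, wts)
}

#' Model specifications for the cross-validation engine
#'
#' A `model_spec` is a plain list with `fit(X, y)`, `predict(model, X)` and
#' a `label`; [brain_age()] and [grid_search_models()] consume them.
#'
#' @param alphas ridge penalty grid.
#' @return A model spec list.
#' @export
model_ridge_cv <- function(alphas = 10^seq(-3, 5, length.out = 13)) {
  list(fit = function(X, y) ridge_cv_fit(X, y, alphas = alphas),
       predict = function(model, X) predict(model, X),
       label = "ridge_cv")
}

#' @rdname model_ridge_cv
#' @param base base model spec to boost.
#' @param n_estimators,learning_rate,seed boosting parameters.
#' @export
model_adaboost <- function(base = model_ridge_cv(), n_estimators = 50,
                           learning_rate = 1, seed = 1L) {
  list(fit = function(X, y) adaboost_r2_fit(X, y, base = base,
                                            n_estimators = n_estimators,
                                            learning_rate = learning_rate,
                                            seed = seed),
       predict = function(model, X) predict(model, X),
       label = sprintf("adaboost(%s)", base$label))
}

# ---- Bias correction and metrics -------------------------------------------

#' Fit the age-prediction bias model
#'
#' Ordinary least squares of the raw predictions on chronological age,
#' `z = a c + b`, fitted on training folds only.
#'
#' @param train_z raw predictions, years.
#' @param train_c chronological ages, years.
#' @return Named vector `c(a = slope, b = intercept)`.
#' @export
fit_bias_correction <- function(train_z, train_c) {
  if (length(train_z) < 3) abort_data("need at least 3 training points")
  vc <- stats::var(train_c)
  if (vc == 0) abort_degenerate("zero variance in training ages")
  a <- stats::cov(train_z, train_c) / vc
  b <- mean(train_z) - a * mean(train_c)
  if (abs(a) < 1e-6)
    abort_degenerate("bias slope ~ 0: correction undefined")
  c(a = a, b = b)
}

#' Apply the bias correction
#'
#' Inverts the fitted prediction-on-age line: `z' = (z - b) / a`. Applied
#' identically to train and test predictions using train-fold coefficients
#' only, so there is no leakage.
#'
#' @param z raw predictions, years.
#' @param a,b slope and intercept from [fit_bias_correction()].
#' @return Corrected predictions, years.
#' @export
apply_bias_correction <- function(z, a, b) {
  if (a == 0) abort_degenerate("zero slope: correction undefined")
  (z - b) / a
}

#' Regression metrics
#'
#' @param pred,truth numeric vectors, years.
#' @return Named vector `c(mae, r2)`: mean absolute error and
#'   `1 - SSres/SStot`.
#' @export
regression_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) abort_shape("length mismatch")
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) abort_degenerate("zero-variance truth: R^2 undefined")
  c(mae = mean(abs(pred - truth)),
    r2 = 1 - sum((pred - truth)^2) / sst)
}

# ---- The cross-validated brain-age model -----------------------------------

#' Brain-age model with repeated stratified cross-validation and bias
#' correction
#'
#' For every repeat and fold: features are standardised using training-fold
#' statistics only, the model is fitted on the training rows, raw
#' predictions are stored for train and test rows, the bias line `z = ac+b`
#' is fitted on the training predictions and inverted (`z' = (z-b)/a`) for
#' both splits. Per-subject summaries average each subject's test-fold and
#' train-fold predictions separately across repeats; the brain-age delta is
#' the corrected test prediction minus chronological age (positive = brain
#' appears older).
#'
#' @param X subjects x features matrix or data frame.
#' @param age chronological ages, years.
#' @param scheme a [cv_scheme()].
#' @param model a model spec ([model_ridge_cv()], [model_adaboost()], ...).
#' @param subject_id optional labels.
#' @return Object of class `brain_age` with `subjects` (per-subject table),
#'   `folds` (per-fold metrics and correction coefficients) and `scheme`.
#' @export
brain_age <- function(X, age, scheme = cv_scheme(), model = model_ridge_cv(),
                      subject_id = NULL) {
  X <- as.matrix(X); age <- as.numeric(age)
  if (nrow(X) != length(age)) abort_shape("X rows must match length of age")
  if (anyNA(X)) abort_data("missing feature values are not supported")
  n <- nrow(X)
  if (is.null(subject_id)) subject_id <- sprintf("sub%04d", seq_len(n))
  folds <- stratified_repeated_kfold(age, scheme)
  acc <- list(
    test_raw = numeric(n), test_cor = numeric(n), test_n = numeric(n),
    train_raw = numeric(n), train_cor = numeric(n), train_n = numeric(n))
  fold_rows <- list()
  n_failed <- 0L
  for (r in seq_len(scheme$repeats)) {
    for (f in seq_len(scheme$k)) {
      te <- which(folds[, r] == f)
      tr <- setdiff(seq_len(n), te)
      if (!length(te)) next
      res <- tryCatch({
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
        sdv[sdv == 0] <- 1
        Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
        Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
        fit <- model$fit(Ztr, age[tr])
        z_tr <- model$predict(fit, Ztr)
        z_te <- model$predict(fit, Zte)
        ab <- fit_bias_correction(z_tr, age[tr])
        zc_tr <- apply_bias_correction(z_tr, ab["a"], ab["b"])
        zc_te <- apply_bias_correction(z_te, ab["a"], ab["b"])
        list(z_tr = z_tr, z_te = z_te, zc_tr = zc_tr, zc_te = zc_te, ab = ab)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        if (n_failed > 0.1 * scheme$repeats * scheme$k)
          abort("more than 10% of folds failed; last error: " %+%
                  conditionMessage(res), "oscillage_cv_error")
        next
      }
      acc$test_raw[te] <- acc$test_raw[te] + res$z_te
      acc$test_cor[te] <- acc$test_cor[te] + res$zc_te
      acc$test_n[te] <- acc$test_n[te] + 1
      acc$train_raw[tr] <- acc$train_raw[tr] + res$z_tr
      acc$train_cor[tr] <- acc$train_cor[tr] + res$zc_tr
      acc$train_n[tr] <- acc$train_n[tr] + 1
      cal <- fit_bias_correction(res$zc_tr, age[tr])  # slope 1, intercept 0
      m_tr <- regression_metrics(res$z_tr, age[tr])
      m_te <- regression_metrics(res$z_te, age[te])
      mc_tr <- regression_metrics(res$zc_tr, age[tr])
      mc_te <- regression_metrics(res$zc_te, age[te])
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        rep = r, fold = f, a = unname(res$ab["a"]), b = unname(res$ab["b"]),
        slope_train_corrected = unname(cal["a"]),
        intercept_train_corrected = unname(cal["b"]),
        mae_train = m_tr["mae"], r2_train = m_tr["r2"],
        mae_test = m_te["mae"], r2_test = m_te["r2"],
        mae_train_corrected = mc_tr["mae"], r2_train_corrected = mc_tr["r2"],
        mae_test_corrected = mc_te["mae"], r2_test_corrected = mc_te["r2"],
        row.names = NULL)
    }
  }
  if (!length(fold_rows)) abort("every fold failed", "oscillage_cv_error")
  subjects <- data.frame(
    subject_id = subject_id, age = age,
    z_train = acc$train_raw / pmax(acc$train_n, 1),
    z_test = acc$test_raw / pmax(acc$test_n, 1),
    z_train_corrected = acc$train_cor / pmax(acc$train_n, 1),
    z_test_corrected = acc$test_cor / pmax(acc$test_n, 1),
    stringsAsFactors = FALSE)
  subjects$delta <- subjects$z_test_corrected - subjects$age
  structure(list(subjects = subjects, folds = do.call(rbind, fold_rows),
                 scheme = scheme, model_label = model$label,
                 n_failed_folds = n_failed),
            class = "brain_age")
}

#' @export
print.brain_age <- function(x, ...) {
  f <- x$folds
  cat(sprintf("<brain_age> %s, %d subjects, k = %d x %d repeats\n",
              x$model_label, nrow(x$subjects), x$scheme$k, x$scheme$repeats))
  cat(sprintf("  raw:       train MAE %.2f +/- %.2f, test MAE %.2f +/- %.2f years\n",
              mean(f$mae_train), stats::sd(f$mae_train),
              mean(f$mae_test), stats::sd(f$mae_test)))
  cat(sprintf("  corrected: train MAE %.2f +/- %.2f, test MAE %.2f +/- %.2f years\n",
              mean(f$mae_train_corrected), stats::sd(f$mae_train_corrected),
              mean(f$mae_test_corrected), stats::sd(f$mae_test_corrected)))
  cat(sprintf("  test R^2: raw %.3f, corrected %.3f\n",
              mean(f$r2_test), mean(f$r2_test_corrected)))
  invisible(x)
}

#' @export
summary.brain_age <- function(object, ...) {
  print(object)
  s <- object$subjects
  slope_raw <- stats::coef(stats::lm(z_test ~ age, data = s))[2]
  slope_cor <- stats::coef(stats::lm(z_test_corrected ~ age, data = s))[2]
  cat(sprintf("  prediction-on-age slope: raw test %.3f, corrected test %.3f\n",
              slope_raw, slope_cor))
  cat(sprintf("  brain-age delta: mean %.2f, SD %.2f years\n",
              mean(s$delta), stats::sd(s$delta)))
  invisible(object)
}

#' @export
plot.brain_age <- function(x, ...) {
  s <- x$subjects
  rng <- range(c(s$age, s$z_test, s$z_test_corrected))
  graphics::plot(s$age, s$z_test, pch = 1, col = "grey40",
                 xlim = rng, ylim = rng,
                 xlab = "chronological age (years)",
                 ylab = "predicted age (years)", ...)
  graphics::points(s$age, s$z_test_corrected, pch = 16, col = "steelblue")
  graphics::abline(0, 1, lty = 2)
  graphics::abline(stats::lm(z_test ~ age, data = s), col = "grey40")
  graphics::abline(stats::lm(z_test_corrected ~ age, data = s), col = "steelblue")
  graphics::legend("topleft", c("raw test", "bias-corrected test"),
                   pch = c(1, 16), col = c("grey40", "steelblue"), bty = "n")
  invisible(x)
}

#' Cross-validated model comparison
#'
#' Runs every candidate through the same cross-validation and ranks them by
#' the sum of mean test MAE and the absolute train-test MAE gap — a
#' selection key that penalises overfitting alongside error.
#'
#' @param candidates named list of model specs.
#' @param X,age,scheme as in [brain_age()].
#' @return Data frame ranked by the selection key (best first).
#' @export
grid_search_models <- function(candidates, X, age, scheme = cv_scheme()) {
  if (!length(candidates)) abort_config("need at least one candidate")
  rows <- lapply(seq_along(candidates), function(i) {
    ba <- brain_age(X, age, scheme = scheme, model = candidates[[i]])
    f <- ba$folds
    data.frame(model = names(candidates)[i] %||% candidates[[i]]$label,
               mae_test = mean(f$mae_test), mae_train = mean(f$mae_train),
               gap = mean(f$mae_train) - mean(f$mae_test),
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab$selection_key <- tab$mae_test + abs(tab$gap)
  tab[order(tab$selection_key), , drop = FALSE]
}
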