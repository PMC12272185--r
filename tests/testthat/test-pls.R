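test_that("preparation z-scores columns and refuses constant ones", {
  set.seed(1)
  X <- matrix(rnorm(50 * 4), 50); Y <- cbind(age = runif(50, 18, 83))
  inp <- pls_prepare(X, Y)
  expect_lt(max(abs(colMeans(inp$X))), 1e-12)
  expect_lt(max(abs(apply(inp$X, 2, sd) - 1)), 1e-12)
  # already standardised input is unchanged
  inp2 <- pls_prepare(inp$X, inp$Y)
  expect_equal(unclass(inp2$X)[, ], unclass(inp$X)[, ], tolerance = 1e-12)
  Ybad <- cbind(age = runif(50), sex = rep(1, 50))
  err <- tryCatch(pls_prepare(X, Ybad), error = identity)
  expect_s3_class(err, "oscillage_degenerate_error")
  expect_match(conditionMessage(err), "sex")
})

test_that("the SVD decomposition satisfies its algebraic identities", {
  set.seed(2)
  n <- 120
  X <- matrix(rnorm(n * 10), n)
  Y <- cbind(X[, 3] + rnorm(n, sd = 0.5), rnorm(n), rnorm(n))
  inp <- pls_prepare(X, Y)
  fit <- pls_svd(inp)
  k <- length(fit$singular_values)
  expect_equal(crossprod(fit$U), diag(ncol(Y)), tolerance = 1e-8)
  expect_equal(crossprod(fit$V)[1:k, 1:k], diag(k), tolerance = 1e-8)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  expect_true(all(fit$singular_values >= 0))
  # reconstruction U D V' = Y'X
  R <- crossprod(inp$Y, inp$X)
  expect_lt(max(abs(fit$U %*% diag(fit$singular_values) %*% t(fit$V) - R)) /
              max(abs(R)), 1e-8)
  # paired score covariance reproduces each singular value
  for (i in seq_len(k))
    expect_equal(stats::cov(fit$Lx[, i], fit$Ly[, i]) * (n - 1),
                 fit$singular_values[i], tolerance = 1e-8)
  # the aligned feature carries the largest salience
  n2 <- 500
  X2 <- matrix(rnorm(n2 * 8), n2)
  Y2 <- cbind(X2[, 5], rnorm(n2))
  fit2 <- pls_svd(pls_prepare(X2, Y2))
  expect_equal(unname(which.max(abs(fit2$V[, 1]))), 5L)
})

test_that("first-component covariance is optimal over random unit pairs", {
  set.seed(3)
  n <- 100
  X <- matrix(rnorm(n * 8), n)
  Y <- X[, 1:3] + matrix(rnorm(n * 3), n)
  inp <- pls_prepare(X, Y)
  fit <- pls_svd(inp)
  c1 <- c(stats::cov(inp$X %*% fit$V[, 1], inp$Y %*% fit$U[, 1]))
  rand <- replicate(10000, {
    v <- rnorm(8); v <- v / sqrt(sum(v^2))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    c(stats::cov(inp$X %*% v, inp$Y %*% u))
  })
  expect_true(all(c1 >= rand - 1e-12))
})

test_that("permutation p-values are valid and powered", {
  set.seed(4)
  # planted latent is detected
  n <- 200; p <- 50
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  lat <- rnorm(n)
  X <- sqrt(p) * lat %*% t(w) + matrix(rnorm(n * p), n)
  Y <- cbind(age = lat + rnorm(n))
  inp <- pls_prepare(X, Y)
  pv <- pls_permutation(inp, n_perm = 199, seed = 9)
  expect_lte(pv[1], 0.05)
  expect_gte(min(pv), 1 / 200)                 # lower bound of the estimator
  # deterministic given seed
  expect_identical(pv, pls_permutation(inp, n_perm = 199, seed = 9))
  expect_error(pls_permutation(inp, n_perm = 50),
               class = "oscillage_config_error")
})

test_that("bootstrap intervals behave at the monotone and null extremes", {
  set.seed(5)
  n <- 80
  lat <- rnorm(n)
  X <- lat %*% t(rep(1, 5)) * 2 + matrix(rnorm(n * 5, sd = 0.01), n)
  Y <- cbind(age = lat)
  inp <- pls_prepare(X, Y)
  fit <- pls_svd(inp)
  ci <- pls_bootstrap(inp, fit, n_boot = 200, seed = 3)
  # Ly is essentially Y itself: Spearman pinned at 1
  expect_gt(ci[1, "age", "lower"], 0.999)
  expect_equal(ci[1, "age", "estimate"], 1, tolerance = 1e-6)
  # null coverage: with several metadata columns the CI for the age
  # correlation usually covers 0
  covers <- vapply(1:20, function(s) {
    set.seed(400 + s)
    Xn <- matrix(rnorm(200 * 5), 200)
    Yn <- cbind(age = rnorm(200), sex = rnorm(200))
    inpn <- pls_prepare(Xn, Yn)
    cin <- pls_bootstrap(inpn, pls_svd(inpn), n_boot = 150, seed = s)
    cin[1, "age", "lower"] <= 0 && cin[1, "age", "upper"] >= 0
  }, logical(1))
  expect_gte(mean(covers), 0.8)
})

test_that("Spearman correlation handles monotone transforms and ties", {
  a <- c(-2, -1, 0, 1, 2)
  expect_equal(spearman_cor(a, a^3), 1)
  expect_equal(spearman_cor(a, -a), -1)
  # ties against exhaustive mid-rank computation
  set.seed(6)
  for (i in 1:5) {
    x <- sample(1:3, 6, replace = TRUE)
    y <- sample(1:3, 6, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_cor(x, y), stats::cor(rank(x), rank(y)))
  }
  expect_error(spearman_cor(rep(1, 5), a), class = "oscillage_degenerate_error")
})

test_that("Mann-Whitney U matches exhaustive enumeration and the normal limit", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)                         # x-exceeds-y convention
  expect_equal(r$p_value, 0.1)
  expect_gt(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 0.9)
  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, replace = TRUE); y <- sample(1:5, n2, replace = TRUE)
    got <- mann_whitney_u(x, y)
    want <- oracle_mwu_exact(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p)
  }
  # normal approximation close to the exact distribution at n1 = n2 = 15
  x <- rnorm(15); y <- rnorm(15) + 0.4
  p_norm <- mann_whitney_u(x, y)$p_value
  p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(p_norm - p_exact), 0.02)
  # salience comparison wrapper works on magnitudes
  cmp <- compare_salience_magnitudes(c(0.5, -0.6, 0.7), c(0.01, -0.02, 0.03))
  expect_lt(cmp$p_value, 0.15)
})

test_that("the assembled meg_pls object is complete and printable", {
  set.seed(8)
  n <- 60
  lat <- rnorm(n)
  X <- sqrt(10) * lat %*% t(rep(1/sqrt(10), 10)) + matrix(rnorm(n * 10), n)
  Y <- cbind(age = lat + rnorm(n), sex = rnorm(n))
  fit <- meg_pls(X, Y, n_perm = 100, n_boot = 100, seed = 2)
  expect_s3_class(fit, "meg_pls")
  expect_length(fit$p_values, 2)
  expect_equal(dim(fit$boot_ci), c(2, 2, 3))
  expect_output(print(fit), "meg_pls")
  expect_output(summary(fit), "significant")
})

test_that("AEC vectorisation takes the strict upper triangle band-major", {
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M[1, 2] <- M[2, 1] <- 0.5
  M[1, 3] <- M[3, 1] <- -0.2
  M[2, 3] <- M[3, 2] <- 0.9
  cm <- structure(list(values = M, band = "alpha", nodes = rownames(M)),
                  class = "connectivity_matrix")
  v <- vectorise_aec(list(alpha = cm))
  expect_equal(unname(v), c(0.5, -0.2, 0.9))
  expect_equal(names(v), c("alpha.a.b", "alpha.a.c", "alpha.b.c"))
})
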