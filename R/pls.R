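#' Standardise feature and metadata matrices for PLS
#'
#' Column-wise z-scoring (mean 0, SD 1, denominator n - 1) of both blocks,
#' preserving column labels. Constant columns cannot be standardised and
#' raise an error naming them.
#'
#' @param Xraw subjects x features matrix or data frame (MEG features).
#' @param Yraw subjects x metadata matrix or data frame (e.g. age, sex).
#' @return Object of class `pls_input` with standardised `X`, `Y` and the
#'   centering/scaling constants.
#' @export
pls_prepare <- function(Xraw, Yraw) {
  X <- as.matrix(Xraw); Y <- as.matrix(Yraw)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%02d", seq_len(ncol(Y)))
  if (nrow(X) != nrow(Y)) abort_shape("X and Y must have equal row counts")
  zscore <- function(M, label) {
    sds <- apply(M, 2, stats::sd)
    bad <- sds == 0
    if (any(bad))
      abort_degenerate(sprintf("constant %s column(s): %s", label,
                               paste(colnames(M)[bad], collapse = ", ")))
    list(Z = scale(M), mu = colMeans(M), sd = sds)
  }
  xs <- zscore(X, "X"); ys <- zscore(Y, "Y")
  structure(list(X = xs$Z[, , drop = FALSE], Y = ys$Z[, , drop = FALSE],
                 x_center = xs$mu, x_scale = xs$sd,
                 y_center = ys$mu, y_scale = ys$sd),
            class = "pls_input")
}

# Sign convention: flip each component so the largest-|.| feature salience
# is positive.
.pls_fix_signs <- function(sv) {
  for (i in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, i]))
    if (sv$v[j, i] < 0) {
      sv$v[, i] <- -sv$v[, i]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  sv
}

#' PLS cross-decomposition by SVD of the cross-product matrix
#'
#' Computes `R = t(Y) %*% X` on the standardised blocks and its thin SVD
#' `R = U D t(V)`: `U` holds metadata saliences, `V` feature saliences and
#' `D` the singular values, each of which equals (n - 1) times the
#' covariance of the paired subject scores `Lx = X V` and `Ly = Y U`.
#'
#' @param input a [pls_prepare()] result.
#' @return List with `singular_values`, `U`, `V`, `Lx`, `Ly`,
#'   `explained_covariance` (squared singular value fractions).
#' @export
pls_svd <- function(input) {
  stopifnot(inherits(input, "pls_input"))
  R <- crossprod(input$Y, input$X)
  sv <- svd(R)
  sv <- .pls_fix_signs(sv)
  Lx <- input$X %*% sv$v
  Ly <- input$Y %*% sv$u
  rownames(sv$u) <- colnames(input$Y)
  rownames(sv$v) <- colnames(input$X)
  list(singular_values = sv$d, U = sv$u, V = sv$v, Lx = Lx, Ly = Ly,
       explained_covariance = sv$d^2 / sum(sv$d^2))
}

#' Permutation test of PLS singular values
#'
#' Permutes the rows of X (Y fixed), recomputes the SVD of the cross-product
#' under the no-association null, and returns per-component p-values
#' `(1 + #{d* >= d}) / (1 + n_perm)`.
#'
#' @param input a [pls_prepare()] result.
#' @param fit a [pls_svd()] result for the unpermuted data.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return Numeric vector of p-values, one per component.
#' @export
pls_permutation <- function(input, fit = pls_svd(input), n_perm = 1000,
                            seed = 1L) {
  if (n_perm < 100) abort_config("n_perm must be at least 100")
  n <- nrow(input$X)
  if (n < 10) warning("fewer than 10 subjects: permutation resolution is poor")
  d0 <- fit$singular_values
  counts <- numeric(length(d0))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      dp <- svd(crossprod(input$Y, input$X[sample.int(n), , drop = FALSE]),
                nu = 0, nv = 0)$d
      counts <- counts + (dp >= d0)
    }
  })
  (1 + counts) / (1 + n_perm)
}

#' Bootstrap confidence intervals of score-metadata correlations
#'
#' Resamples subjects with replacement, recomputes the PLS SVD per resample
#' (sign-aligned to the original solution), and correlates each Ly score
#' column with each Y metadata column by Spearman rank correlation;
#' percentile intervals are returned. Resamples producing a constant column
#' are redrawn (count recorded).
#'
#' @param input a [pls_prepare()] result.
#' @param fit a [pls_svd()] result.
#' @param n_boot number of resamples (>= 100; default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return Array components x Y-columns x (lower, estimate, upper); number
#'   of redraws in attribute `"n_redrawn"`.
#' @export
pls_bootstrap <- function(input, fit = pls_svd(input), n_boot = 1000,
                          seed = 1L, level = 0.95) {
  if (n_boot < 100) abort_config("n_boot must be at least 100")
  n <- nrow(input$X); q <- ncol(input$Y)
  k <- length(fit$singular_values)
  vals <- array(NA_real_, c(n_boot, k, q))
  redrawn <- 0L
  with_seed(seed, {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, replace = TRUE)
      Xb <- input$X[idx, , drop = FALSE]; Yb <- input$Y[idx, , drop = FALSE]
      if (any(apply(Xb, 2, stats::sd) == 0) || any(apply(Yb, 2, stats::sd) == 0)) {
        redrawn <- redrawn + 1L
        if (redrawn > 10L * n_boot)
          abort_degenerate("too many degenerate bootstrap resamples")
        next
      }
      sv <- svd(crossprod(Yb, Xb))
      # sign-align to the original solution
      for (i in seq_len(k)) {
        if (sum(sv$v[, i] * fit$V[, i]) < 0) {
          sv$v[, i] <- -sv$v[, i]; sv$u[, i] <- -sv$u[, i]
        }
      }
      Lyb <- Yb %*% sv$u[, seq_len(k), drop = FALSE]
      for (i in seq_len(k)) for (j in seq_len(q))
        vals[b, i, j] <- spearman_cor(Lyb[, i], Yb[, j])
      b <- b + 1L
    }
  })
  alpha <- (1 - level) / 2
  out <- array(NA_real_, c(k, q, 3),
               dimnames = list(paste0("comp", seq_len(k)), colnames(input$Y),
                               c("lower", "estimate", "upper")))
  for (i in seq_len(k)) for (j in seq_len(q)) {
    v <- vals[, i, j]
    out[i, j, ] <- c(stats::quantile(v, alpha, na.rm = TRUE),
                     spearman_cor(fit$Ly[, i], input$Y[, j]),
                     stats::quantile(v, 1 - alpha, na.rm = TRUE))
  }
  attr(out, "n_redrawn") <- redrawn
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties); errors on
#' constant input, for which the correlation is undefined.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_cor <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    abort_shape("need equal lengths of at least 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort_degenerate("Spearman correlation undefined for constant input")
  stats::cor(a, b, method = "spearman")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` counts pairs where a value of `x` exceeds a
#' value of `y` (ties count one half). For total sample size <= 20 the null
#' distribution is enumerated exhaustively over all group assignments of
#' the observed values (exact even under ties); otherwise the normal
#' approximation with tie correction is used. The two-sided p-value is the
#' null probability of a U at least as far from n1*n2/2 as observed.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_limit maximum total size for exhaustive enumeration.
#' @return List with `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort_shape("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  if (n1 + n2 <= exact_limit) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Us - center) >= abs(U - center) - 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (U - center) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p_value = min(p, 1), method = method)
}

#' Compare salience magnitudes between feature families
#'
#' Two-sided Mann-Whitney U on the absolute PLS saliences of two feature
#' groups (e.g. spectral power vs connectivity), asking whether one family
#' carries systematically larger loadings.
#'
#' @param power_saliences,conn_saliences numeric vectors of saliences.
#' @return As [mann_whitney_u()].
#' @export
compare_salience_magnitudes <- function(power_saliences, conn_saliences) {
  mann_whitney_u(abs(power_saliences), abs(conn_saliences))
}

#' Vectorise connectivity matrices for PLS
#'
#' Strict upper triangle of each band's matrix, band-major column order,
#' with `band.nodei.nodej` labels.
#'
#' @param aec_list named list of [aec_matrix()] results (one subject).
#' @return Named numeric vector; rbind across subjects to build a cohort
#'   feature block.
#' @export
vectorise_aec <- function(aec_list) {
  out <- lapply(names(aec_list), function(b) {
    M <- aec_list[[b]]$values
    ut <- which(upper.tri(M), arr.ind = TRUE)
    v <- M[upper.tri(M)]
    names(v) <- paste(b, rownames(M)[ut[, 1]], colnames(M)[ut[, 2]], sep = ".")
    v
  })
  unlist(out)
}

#' Partial least squares analysis of MEG features against metadata
#'
#' The full inference procedure: column standardisation of both blocks, SVD
#' of the cross-product matrix, permutation test of the singular values
#' (rows of X shuffled, alpha = 0.05), and bootstrap percentile confidence
#' intervals for the Spearman correlations between subject scores and
#' metadata columns.
#'
#' @param X subjects x features matrix (band power and/or vectorised AEC).
#' @param Y subjects x metadata matrix (age, sex coding, ...).
#' @param n_perm permutations (default 1000).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level bootstrap confidence level.
#' @return Object of class `meg_pls`: the [pls_svd()] fields plus
#'   `p_values`, `boot_ci`, `n`, and the prepared input.
#' @export
meg_pls <- function(X, Y, n_perm = 1000, n_boot = 1000, seed = 1L,
                    level = 0.95) {
  input <- pls_prepare(X, Y)
  fit <- pls_svd(input)
  fit$p_values <- pls_permutation(input, fit, n_perm = n_perm,
                                  seed = stage_seed(seed, "pls_perm"))
  fit$boot_ci <- pls_bootstrap(input, fit, n_boot = n_boot,
                               seed = stage_seed(seed, "pls_boot"),
                               level = level)
  fit$n <- nrow(input$X)
  fit$input <- input
  class(fit) <- "meg_pls"
  fit
}

#' @export
print.meg_pls <- function(x, ...) {
  cat(sprintf("<meg_pls> n = %d subjects, %d features, %d metadata columns\n",
              x$n, nrow(x$V), nrow(x$U)))
  tab <- data.frame(component = seq_along(x$singular_values),
                    singular_value = signif(x$singular_values, 4),
                    explained_cov = signif(x$explained_covariance, 3),
                    p_value = signif(x$p_values, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.meg_pls <- function(object, alpha = 0.05, ...) {
  sig <- which(object$p_values <= alpha)
  cat(sprintf("PLS: %d of %d components significant at alpha = %g\n",
              length(sig), length(object$p_values), alpha))
  print(object)
  if (length(sig)) {
    cat("\nBootstrap CIs of score-metadata Spearman correlations (component 1):\n")
    print(signif(object$boot_ci[1, , ], 3))
  }
  invisible(object)
}
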