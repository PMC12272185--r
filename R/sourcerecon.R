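#' Source time course container
#'
#' @param data nodes x samples matrix (unit-SD arbitrary units after
#'   reconstruction).
#' @param rate sampling rate, Hz.
#' @param nodes node labels.
#' @param epoch_bounds optional integer vector of per-epoch sample counts.
#' @param subject_id optional subject label.
#' @return An object of class `source_tc`.
#' @export
source_tc <- function(data, rate, nodes = NULL, epoch_bounds = NULL,
                      subject_id = NULL) {
  data <- as.matrix(data)
  if (is.null(nodes)) nodes <- sprintf("node%03d", seq_len(nrow(data)))
  if (length(nodes) != nrow(data)) abort_shape("node labels must match row count")
  structure(list(data = data, rate = rate, nodes = as.character(nodes),
                 epoch_bounds = epoch_bounds, subject_id = subject_id),
            class = "source_tc")
}

#' @export
print.source_tc <- function(x, ...) {
  cat(sprintf("<source_tc> %d nodes x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Sensor covariance from concatenated epochs
#'
#' Concatenates all epochs in time, removes per-channel means, and returns
#' the sample covariance (denominator n - 1) in fT^2.
#'
#' @param es an [epoch_set()].
#' @return An object of class `sensor_covariance` with fields `matrix` and
#'   `n_samples_used`.
#' @export
data_covariance <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  X <- do.call(cbind, es$epochs)
  n <- ncol(X)
  if (n < 2L) abort_degenerate("need at least 2 samples for a covariance")
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (n - 1)
  C <- (C + t(C)) / 2
  structure(list(matrix = C, n_samples_used = n), class = "sensor_covariance")
}

#' Tikhonov regularisation of a covariance matrix
#'
#' Adds `fraction` of the maximum singular value to the diagonal
#' (default 5%), shifting every eigenvalue by exactly that amount so the
#' matrix is safely invertible before beamforming.
#'
#' @param C a [data_covariance()] result (or plain matrix).
#' @param fraction non-negative regularisation fraction (default 0.05).
#' @return A `sensor_covariance` with the regularised matrix.
#' @export
tikhonov_regularise <- function(C, fraction = 0.05) {
  M <- if (inherits(C, "sensor_covariance")) C$matrix else as.matrix(C)
  if (fraction < 0) abort_config("fraction must be non-negative")
  smax <- norm(M, type = "2")
  R <- M + diag(fraction * smax, nrow(M))
  structure(list(matrix = R,
                 n_samples_used = if (inherits(C, "sensor_covariance"))
                   C$n_samples_used else NA_integer_),
            class = "sensor_covariance")
}

#' LCMV scalar beamformer weights with max-power orientation
#'
#' Computes the linearly-constrained minimum-variance spatial filter for one
#' source location. The source orientation is chosen to maximise the
#' unit-gain beamformer output power: the eigenvector of the smallest
#' eigenvalue of `t(H) C^-1 H`, with the search restricted to the
#' numerically non-silent subspace of the lead field (in a spherical
#' conductor the radial direction is magnetically silent, so H has effective
#' rank 2). The weight vector is `C^-1 h / (t(h) C^-1 h)` with `h = H theta`,
#' which satisfies unit gain `t(w) h = 1` exactly. `nai_scale = t(h) h` is
#' stored for neural-activity-index normalisation.
#'
#' @param C_reg regularised [tikhonov_regularise()] covariance.
#' @param H a [sphere_lead_field()] (or channels x 3 matrix).
#' @param rank_tol relative singular-value tolerance deciding which lead
#'   field directions count as silent.
#' @return An object of class `beamformer_weights` with fields `w`,
#'   `orientation`, `nai_scale` and `source_id`.
#' @export
lcmv_scalar_weights <- function(C_reg, H, rank_tol = 1e-8) {
  M <- if (inherits(C_reg, "sensor_covariance")) C_reg$matrix else as.matrix(C_reg)
  G <- if (inherits(H, "lead_field")) H$gains else as.matrix(H)
  if (nrow(G) != nrow(M)) abort_shape("lead field and covariance channel counts differ")
  Ci <- tryCatch(chol2inv(chol(M)),
                 error = function(e) abort_numeric(
                   "covariance not positive definite; apply Tikhonov regularisation first"))
  sv <- svd(G)
  keep <- sv$d > rank_tol * sv$d[1]
  if (!any(keep))
    abort_geometry("lead field is numerically zero (rank-deficient geometry)")
  Vk <- sv$v[, keep, drop = FALSE]
  Hk <- G %*% Vk
  Gram <- crossprod(Hk, Ci %*% Hk)
  Gram <- (Gram + t(Gram)) / 2
  eg <- eigen(Gram, symmetric = TRUE)
  xi <- eg$vectors[, which.min(eg$values)]
  theta <- as.numeric(Vk %*% xi)
  theta <- theta / vnorm(theta)
  nz <- which(abs(theta) > 1e-12)[1]
  if (theta[nz] < 0) theta <- -theta
  h <- as.numeric(G %*% theta)
  denom <- as.numeric(crossprod(h, Ci %*% h))
  w <- as.numeric(Ci %*% h) / denom
  gain <- sum(w * h)
  if (abs(gain - 1) > 1e-8)
    abort_numeric(sprintf("unit-gain constraint violated (|wh - 1| = %.2e)",
                          abs(gain - 1)))
  structure(list(w = w, orientation = theta, nai_scale = sum(h^2),
                 source_id = if (inherits(H, "lead_field")) H$source_id else "src"),
            class = "beamformer_weights")
}

#' Apply beamformer weights to epoched sensor data
#'
#' Projects each epoch through every weight vector and concatenates in time.
#' With `nai = TRUE` each node's time course is divided by
#' `sqrt(nai_scale)` (neural activity index normalisation, countering depth-
#' dependent noise amplification); finally every node is independently
#' scaled to unit standard deviation, which makes all downstream band-power
#' and connectivity features invariant to the NAI choice.
#'
#' @param es an [epoch_set()].
#' @param weights list of [lcmv_scalar_weights()] results.
#' @param nai logical; apply neural-activity-index normalisation.
#' @param subject_id optional label carried into the output.
#' @return A [source_tc()] with one row per weight set.
#' @export
apply_weights <- function(es, weights, nai = TRUE, subject_id = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  if (inherits(weights, "beamformer_weights")) weights <- list(weights)
  m <- nrow(es$epochs[[1]])
  W <- t(vapply(weights, function(b) {
    if (length(b$w) != m) abort_shape("weight length does not match channel count")
    b$w
  }, numeric(m)))
  X <- do.call(cbind, es$epochs)
  S <- W %*% X
  if (nai) {
    scl <- sqrt(vapply(weights, function(b) b$nai_scale, numeric(1)))
    S <- S / scl
  }
  sds <- apply(S, 1, stats::sd)
  if (any(sds <= 0)) abort_degenerate("zero-variance source time course")
  S <- S / sds
  source_tc(S, es$rate,
            nodes = vapply(weights, function(b) b$source_id, character(1)),
            epoch_bounds = vapply(es$epochs, ncol, integer(1)),
            subject_id = subject_id)
}
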