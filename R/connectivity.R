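#' Band-pass filter source time courses
#'
#' Applies the same zero-phase Hamming-window FIR design used at sensor
#' level to every node of a [source_tc()], with the band's edges.
#'
#' @param stcs a [source_tc()].
#' @param low,high band edges, Hz.
#' @return A filtered [source_tc()].
#' @export
band_filter_stcs <- function(stcs, low, high) {
  stopifnot(inherits(stcs, "source_tc"))
  if (!(low > 0 && low < high && high < stcs$rate / 2))
    abort_config("band edges must satisfy 0 < low < high < Nyquist")
  tw <- min(.transition_bw(low), .transition_bw(high))
  kernel <- .fir_kernel(stcs$rate, c(low, high), "pass", tw)
  source_tc(.apply_fir(stcs$data, kernel), stcs$rate, stcs$nodes,
            stcs$epoch_bounds, stcs$subject_id)
}

#' Symmetric (Loewdin) orthogonalisation of node time courses
#'
#' Finds the set of mutually zero-lag-uncorrelated signals closest in the
#' least-squares sense to the input rows, treating all nodes equivalently:
#' alternately project onto the closest orthonormal frame (polar/SVD step)
#' and refit per-node scales, iterating until the relative change falls
#' below `tol`. Rows are demeaned first, and because every output signal is
#' a linear combination of the inputs the outputs stay zero-mean, so their
#' pairwise Pearson correlations vanish at machine precision. This removes
#' the spurious zero-lag correlations introduced by field spread / source
#' leakage before envelope correlation.
#'
#' @param X nodes x samples matrix (or [source_tc()]), more samples than
#'   nodes, full row rank.
#' @param tol relative convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 300).
#' @return Object of the same kind as the input with orthogonalised rows.
#' @export
symmetric_orthogonalise <- function(X, tol = 1e-10, max_iter = 300) {
  stc <- NULL
  if (inherits(X, "source_tc")) { stc <- X; X <- X$data }
  X <- as.matrix(X)
  n <- nrow(X); T_ <- ncol(X)
  if (T_ <= n) abort_shape("need more samples than nodes")
  A <- t(X - rowMeans(X))                 # T x n, zero-mean columns
  qrA <- qr(A)
  if (qrA$rank < n)
    abort_rank(sprintf("input has rank %d < %d nodes; cannot orthogonalise",
                       qrA$rank, n))
  d <- sqrt(colSums(A^2))
  total <- sum(A^2)
  err_prev <- Inf
  O <- NULL
  for (it in seq_len(max_iter)) {
    sv <- svd(A %*% diag(d, n))
    O <- sv$u %*% t(sv$v)                 # closest orthonormal frame
    d <- colSums(A * O)                   # per-node least-squares scales
    err <- sum((A - O %*% diag(d, n))^2)
    if (is.finite(err_prev) && abs(err_prev - err) <= tol * total) {
      err_prev <- err
      break
    }
    err_prev <- err
    if (it == max_iter)
      abort_convergence(sprintf(
        "symmetric orthogonalisation did not converge in %d iterations (residual %.3e)",
        max_iter, err))
  }
  out <- t(O %*% diag(d, n))
  if (!is.null(stc))
    return(source_tc(out, stc$rate, stc$nodes, stc$epoch_bounds, stc$subject_id))
  out
}

#' Hilbert amplitude envelope
#'
#' Modulus of the analytic signal, computed by zeroing negative frequencies
#' in the FFT; non-negative by construction.
#'
#' @param x numeric vector.
#' @return Numeric vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) abort_numeric("signal contains non-finite samples")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Downsample an envelope by block averaging
#'
#' Non-overlapping block means over consecutive windows of `1/target`
#' seconds; only complete blocks are returned (250 s at any rate yields
#' 250 samples at the default 1 Hz).
#'
#' @param env numeric vector sampled at `rate`.
#' @param rate input sampling rate, Hz.
#' @param target output rate, Hz (default 1).
#' @return Numeric vector of block means.
#' @export
downsample_envelope <- function(env, rate, target = 1) {
  env <- as.numeric(env)
  if (rate < target) abort_config("rate must be at least the target rate")
  block <- rate / target
  n_out <- floor(length(env) / block)
  if (n_out < 2L) abort_data("need at least 2 complete one-over-target-second windows")
  idx <- floor((seq_len(floor(n_out * block)) - 1) / block)
  as.numeric(tapply(env[seq_along(idx)], idx, mean))
}

#' Amplitude envelope correlation matrix
#'
#' Pearson correlation between every pair of (downsampled) node envelopes.
#' Symmetric with the diagonal forced to zero (self-coupling is undefined
#' after orthogonalisation). A zero-variance node is flagged with a warning
#' and its row/column set to NA.
#'
#' @param envs nodes x samples matrix of envelopes.
#' @param band band label stored with the result.
#' @param nodes node labels.
#' @return Object of class `connectivity_matrix`: fields `values`, `band`,
#'   `nodes`.
#' @export
aec_matrix <- function(envs, band = "band", nodes = NULL) {
  envs <- as.matrix(envs)
  if (ncol(envs) < 3L) abort_data("need at least 3 envelope samples")
  if (is.null(nodes)) nodes <- sprintf("node%03d", seq_len(nrow(envs)))
  v <- apply(envs, 1, stats::var)
  R <- matrix(NA_real_, nrow(envs), nrow(envs))
  ok <- v > 0
  if (!all(ok)) warning(sprintf("%d zero-variance node(s) set to NA", sum(!ok)))
  R[ok, ok] <- stats::cor(t(envs[ok, , drop = FALSE]))
  R <- (R + t(R)) / 2
  diag(R) <- 0
  dimnames(R) <- list(nodes, nodes)
  structure(list(values = R, band = band, nodes = as.character(nodes)),
            class = "connectivity_matrix")
}

#' Leakage-corrected amplitude envelope connectivity for one band
#'
#' The full per-band chain: zero-phase band-pass filter, symmetric
#' orthogonalisation on the concatenated time courses, Hilbert envelopes,
#' edge trimming (`edge_trim` seconds each end, suppressing Hilbert edge
#' artefacts), block-mean downsampling to `env_rate`, and Pearson
#' correlation.
#'
#' @param stcs a [source_tc()].
#' @param low,high band edges, Hz.
#' @param band band label.
#' @param env_rate envelope rate after downsampling, Hz (default 1).
#' @param edge_trim seconds trimmed from each end of the envelopes
#'   (default 2).
#' @param orthogonalise logical; set `FALSE` to obtain raw (leaky) AEC.
#' @return A [aec_matrix()] result.
#' @export
band_aec <- function(stcs, low, high, band = "band", env_rate = 1,
                     edge_trim = 2, orthogonalise = TRUE) {
  stopifnot(inherits(stcs, "source_tc"))
  filt <- band_filter_stcs(stcs, low, high)
  sig <- if (orthogonalise) symmetric_orthogonalise(filt$data) else filt$data
  envs <- t(apply(sig, 1, hilbert_envelope))
  trim_n <- round(edge_trim * stcs$rate)
  if (trim_n > 0 && ncol(envs) > 2 * trim_n + 2)
    envs <- envs[, (trim_n + 1):(ncol(envs) - trim_n), drop = FALSE]
  down <- t(apply(envs, 1, downsample_envelope, rate = stcs$rate,
                  target = env_rate))
  aec_matrix(down, band = band, nodes = stcs$nodes)
}

#' All-band envelope connectivity
#'
#' Runs [band_aec()] for every band of the scheme.
#'
#' @param stcs a [source_tc()].
#' @param scheme a [band_scheme()].
#' @param ... passed to [band_aec()].
#' @return Named list of [aec_matrix()] results, one per band.
#' @export
cohort_aec <- function(stcs, scheme = band_scheme(), ...) {
  out <- lapply(seq_len(nrow(scheme)), function(i)
    band_aec(stcs, scheme$low[i], scheme$high[i], band = scheme$name[i], ...))
  stats::setNames(out, scheme$name)
}
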