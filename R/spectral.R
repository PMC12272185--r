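#' Canonical frequency band scheme
#'
#' The five a-priori bands used throughout the pipeline, separated by 1 Hz
#' gaps so no spectral bin belongs to two bands: delta 1-3, theta 4-8,
#' alpha 9-12, beta 13-29, gamma 30-45 Hz.
#'
#' @param bands data frame with columns `name`, `low`, `high` (Hz); defaults
#'   to the canonical five.
#' @return A validated `band_scheme` data frame.
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands))
    bands <- data.frame(
      name = c("delta", "theta", "alpha", "beta", "gamma"),
      low  = c(1, 4, 9, 13, 30),
      high = c(3, 8, 12, 29, 45),
      stringsAsFactors = FALSE)
  if (!all(c("name", "low", "high") %in% names(bands)))
    abort_config("band scheme needs columns name, low, high")
  if (any(bands$low >= bands$high)) abort_config("band low must be below high")
  if (is.unsorted(bands$low) || any(bands$high[-nrow(bands)] >= bands$low[-1]))
    abort_config("bands must be ascending and non-overlapping")
  class(bands) <- c("band_scheme", "data.frame")
  bands
}

#' Welch power spectral density
#'
#' Averages modified periodograms over non-overlapping Hann-tapered segments
#' of `n_fft` samples; a trailing partial segment is discarded. One-sided
#' density scaling: the PSD integrated over 0..rate/2 (bin width
#' `rate/n_fft`) equals the signal variance.
#'
#' @param x numeric vector, one node's time course.
#' @param rate sampling rate, Hz.
#' @param n_fft segment length in samples (default 4096).
#' @return An object of class `power_spectrum` with fields `freqs`, `values`
#'   and `n_segments`.
#' @export
welch_psd <- function(x, rate, n_fft = 4096) {
  x <- as.numeric(x)
  n_seg <- floor(length(x) / n_fft)
  if (n_seg < 1L)
    abort_data(sprintf("need at least %d samples for one Welch segment", n_fft))
  k <- seq_len(n_fft) - 1L
  win <- 0.5 - 0.5 * cos(2 * pi * k / n_fft)   # periodic Hann
  u <- sum(win^2)
  nb <- n_fft %/% 2L + 1L
  acc <- numeric(nb)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1L) * n_fft + 1L):(s * n_fft)] * win
    p <- Mod(stats::fft(seg))^2 / (rate * u)
    p <- p[seq_len(nb)]
    p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]       # one-sided
    acc <- acc + p
  }
  structure(list(freqs = (seq_len(nb) - 1L) * rate / n_fft,
                 values = acc / n_seg, n_segments = n_seg),
            class = "power_spectrum")
}

#' Band-limited relative power
#'
#' For each band, the amplitude is the mean of `sqrt(PSD)` over the bins in
#' the closed interval `[low, high]`; relative power is each band amplitude
#' divided by the sum of the five band amplitudes, so the five values sum to
#' one. Bins in the 1 Hz gaps and above the top band do not contribute.
#'
#' @param spec a [welch_psd()] result.
#' @param scheme a [band_scheme()].
#' @return Named numeric vector of relative band powers, one per band.
#' @export
band_relative_power <- function(spec, scheme = band_scheme()) {
  stopifnot(inherits(spec, "power_spectrum"))
  amps <- vapply(seq_len(nrow(scheme)), function(i) {
    in_band <- spec$freqs >= scheme$low[i] & spec$freqs <= scheme$high[i]
    if (!any(in_band))
      abort_config(sprintf("band %s has no spectral bins", scheme$name[i]))
    mean(sqrt(spec$values[in_band]))
  }, numeric(1))
  stats::setNames(amps / sum(amps), scheme$name)
}

#' Cohort band-power table
#'
#' Computes per-node relative band power for every subject and assembles the
#' wide table used as the feature matrix X: one row per subject, columns in
#' deterministic node-major, band-minor order named `node_band`.
#'
#' @param stcs list of [source_tc()] objects, one per subject, sharing node
#'   labels and rate.
#' @param scheme a [band_scheme()].
#' @param n_fft Welch segment length.
#' @return A data frame with a `subject_id` column followed by
#'   `n_nodes * n_bands` relative-power columns, rows sorted by subject id.
#' @export
cohort_band_power <- function(stcs, scheme = band_scheme(), n_fft = 4096) {
  if (length(stcs) == 0L) abort_data("no subjects supplied")
  nodes <- stcs[[1]]$nodes
  rate <- stcs[[1]]$rate
  for (s in stcs) {
    if (!identical(s$nodes, nodes))
      abort_schema("inconsistent node sets across subjects")
    if (s$rate != rate) abort_schema("inconsistent sampling rates across subjects")
  }
  cols <- as.vector(t(outer(nodes, scheme$name, paste, sep = "_")))
  rows <- lapply(stcs, function(s) {
    vals <- unlist(lapply(seq_along(nodes), function(i)
      band_relative_power(welch_psd(s$data[i, ], rate, n_fft), scheme)))
    stats::setNames(as.numeric(vals), cols)
  })
  ids <- vapply(stcs, function(s) s$subject_id %||% NA_character_, character(1))
  out <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, rows)))
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}
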