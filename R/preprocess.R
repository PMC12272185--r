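#' Sensor recording container
#'
#' @param data channels x samples numeric matrix in fT.
#' @param rate sampling rate, Hz.
#' @param channel_names optional channel labels.
#' @param subject_id optional subject label.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, rate, channel_names = NULL, subject_id = NULL) {
  data <- as.matrix(data)
  if (!is_scalar_number(rate) || rate <= 0) abort_config("rate must be a positive number")
  if (!all(is.finite(data))) abort_numeric("recording contains non-finite samples")
  if (is.null(channel_names)) channel_names <- sprintf("MEG%03d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    abort_shape("channel_names length must match channel count")
  structure(list(data = data, rate = rate,
                 channel_names = as.character(channel_names),
                 subject_id = subject_id),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

# ---- FIR machinery ---------------------------------------------------------

# Transition bandwidth rule: max(2 Hz, 25% of the edge frequency), never
# wider than the edge itself. Gives a 3.3 s impulse response for a 1 Hz edge
# under the ~3.3/transition-width length rule of the Hamming window design.
.transition_bw <- function(edge) min(max(2, 0.25 * edge), edge)

# Odd-length Hamming-window FIR kernel; type as in signal::fir1.
.fir_kernel <- function(rate, w, type, transition) {
  n_taps <- ceiling(3.3 / transition * rate)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  n_taps <- max(n_taps, 11)
  as.numeric(signal::fir1(n_taps - 1, w / (rate / 2), type))
}

# Zero-phase FIR by single-pass convolution with a symmetric odd-length
# kernel and exact group-delay compensation; FFT overlap-free convolution.
.apply_fir <- function(data, kernel) {
  data <- as.matrix(data)
  ns <- ncol(data); nk <- length(kernel); half <- (nk - 1L) / 2L
  nfft <- stats::nextn(ns + nk - 1L, 2)
  K <- stats::fft(c(kernel, numeric(nfft - nk)))
  out <- matrix(0, nrow(data), ns)
  for (ch in seq_len(nrow(data))) {
    X <- stats::fft(c(data[ch, ], numeric(nfft - ns)))
    y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
    out[ch, ] <- y[(half + 1L):(half + ns)]
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every channel with a symmetric (linear-phase) Hamming-window FIR
#' kernel whose group delay is compensated exactly, so the output is
#' zero-phase and the same length as the input. Transition bandwidth per edge
#' is `max(2 Hz, 0.25 x edge)` bounded by the edge itself, which reproduces a
#' 3.3 s impulse response for a 1 Hz lower edge.
#'
#' @param rec a [sensor_recording()].
#' @param low,high band edges in Hz, `0 < low < high < rate/2`.
#' @return A filtered [sensor_recording()].
#' @export
fir_bandpass <- function(rec, low = 1, high = 150) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!(low > 0 && low < high && high < rec$rate / 2))
    abort_config(sprintf("band edges must satisfy 0 < %g < %g < %g (Nyquist)",
                         low, high, rec$rate / 2))
  tw <- min(.transition_bw(low), .transition_bw(high))
  kernel <- .fir_kernel(rec$rate, c(low, high), "pass", tw)
  sensor_recording(.apply_fir(rec$data, kernel), rec$rate,
                   rec$channel_names, rec$subject_id)
}

#' Notch filter for line noise
#'
#' Applies a zero-phase FIR band-stop around each listed frequency
#' (stop band +/- 1.5 Hz, 2 Hz transitions), giving > 30 dB attenuation at
#' the notch frequency while leaving frequencies 5 Hz away within 1 dB.
#'
#' @param rec a [sensor_recording()].
#' @param freqs notch frequencies in Hz; defaults to 50 and 60 Hz mains.
#' @return A filtered [sensor_recording()].
#' @export
notch <- function(rec, freqs = c(50, 60)) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (any(freqs >= rec$rate / 2))
    abort_config("notch frequencies must lie below Nyquist")
  out <- rec$data
  for (f in freqs) {
    kernel <- .fir_kernel(rec$rate, c(f - 1.5, f + 1.5), "stop", 2)
    out <- .apply_fir(out, kernel)
  }
  sensor_recording(out, rec$rate, rec$channel_names, rec$subject_id)
}

#' Resample a recording to a lower rate
#'
#' Anti-alias low-pass filters (zero-phase FIR, cutoff 0.475 x target rate)
#' and then resamples. Integer decimation factors pick every k-th sample;
#' non-integer ratios use cubic-spline interpolation at the new sample times.
#' Upsampling is not supported.
#'
#' @param rec a [sensor_recording()].
#' @param target_rate new sampling rate in Hz (default 300).
#' @return A resampled [sensor_recording()].
#' @export
resample <- function(rec, target_rate = 300) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (target_rate > rec$rate)
    abort("upsampling is not supported", "oscillage_unsupported_error")
  if (target_rate == rec$rate) return(rec)
  kernel <- .fir_kernel(rec$rate, 0.475 * target_rate, "low",
                        0.05 * target_rate)
  filtered <- .apply_fir(rec$data, kernel)
  ns <- ncol(rec$data)
  n_out <- floor(ns * target_rate / rec$rate)
  ratio <- rec$rate / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- 1 + (seq_len(n_out) - 1) * round(ratio)
    out <- filtered[, idx, drop = FALSE]
  } else {
    t_old <- (seq_len(ns) - 1) / rec$rate
    t_new <- (seq_len(n_out) - 1) / target_rate
    out <- t(apply(filtered, 1, function(ch)
      stats::spline(t_old, ch, xout = t_new)$y))
  }
  sensor_recording(out, target_rate, rec$channel_names, rec$subject_id)
}

#' Pass-through hook for external artefact-component removal
#'
#' Accepts an externally supplied list of component time-series/topography
#' pairs (or a projection matrix) to regress out of the data. With no
#' components it returns the recording unchanged. This replaces automated
#' ICA-based artefact classification, which requires labelled ocular/cardiac
#' exemplars that synthetic data does not contain.
#'
#' @param rec a [sensor_recording()].
#' @param projection optional channels x channels matrix applied to the data.
#' @return A [sensor_recording()].
#' @export
remove_components <- function(rec, projection = NULL) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (is.null(projection)) return(rec)
  projection <- as.matrix(projection)
  if (nrow(projection) != nrow(rec$data) || ncol(projection) != nrow(rec$data))
    abort_shape("projection must be channels x channels")
  sensor_recording(projection %*% rec$data, rec$rate,
                   rec$channel_names, rec$subject_id)
}

# ---- Epoching --------------------------------------------------------------

#' Epoch set constructor
#' @param epochs list of equally shaped channels x samples matrices (fT).
#' @param rate sampling rate, Hz.
#' @param epoch_duration epoch length in seconds.
#' @param rejection_log data frame logging per-epoch decisions.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, rate, epoch_duration, rejection_log = NULL) {
  if (length(epochs) > 0) {
    dims <- vapply(epochs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      abort_shape("all epochs must have identical shape")
    if (abs(dims[2, 1] - epoch_duration * rate) > 1)
      abort_shape("epoch sample count inconsistent with duration x rate")
  }
  if (is.null(rejection_log))
    rejection_log <- data.frame(epoch_index = seq_along(epochs),
                                kept = TRUE, reason = "", stringsAsFactors = FALSE)
  structure(list(epochs = epochs, rate = rate, epoch_duration = epoch_duration,
                 rejection_log = rejection_log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %.2f s @ %g Hz\n",
              length(x$epochs), x$epoch_duration, x$rate))
  invisible(x)
}

#' Segment a recording into fixed non-overlapping epochs
#'
#' @param rec a [sensor_recording()].
#' @param duration epoch length in seconds (default 10.24 s, i.e. 3072
#'   samples at 300 Hz). The residual tail shorter than one epoch is dropped.
#' @return An [epoch_set()].
#' @export
epoch <- function(rec, duration = 10.24) {
  stopifnot(inherits(rec, "sensor_recording"))
  spe <- round(duration * rec$rate)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep < 1L)
    abort_data(sprintf("recording (%.2f s) shorter than one epoch (%.2f s)",
                       ncol(rec$data) / rec$rate, duration))
  epochs <- lapply(seq_len(n_ep), function(i)
    rec$data[, ((i - 1) * spe + 1):(i * spe), drop = FALSE])
  epoch_set(epochs, rec$rate, duration)
}

.epoch_ptp <- function(ep) max(apply(ep, 1, function(ch) diff(range(ch))))

#' Amplitude-based epoch rejection
#'
#' Discards epochs whose peak-to-peak amplitude on any channel exceeds
#' `ptp_limit`, and epochs whose high-frequency content (the epoch high-pass
#' filtered above `hf_cutoff`) exceeds `hf_limit` peak-to-peak — a muscle
#' artefact criterion. The rejection log records which rule fired per epoch.
#'
#' @param es an [epoch_set()].
#' @param ptp_limit broadband peak-to-peak limit, fT (default 6000).
#' @param hf_limit high-frequency peak-to-peak limit, fT (default 2000).
#' @param hf_cutoff high-pass edge for the HF criterion, Hz (default 110).
#' @return An [epoch_set()] containing only retained epochs, with a
#'   `rejection_log` covering every input epoch.
#' @export
reject_epochs <- function(es, ptp_limit = 6000, hf_limit = 2000, hf_cutoff = 110) {
  stopifnot(inherits(es, "epoch_set"))
  n <- length(es$epochs)
  ptp <- vapply(es$epochs, .epoch_ptp, numeric(1))
  bad_ptp <- ptp > ptp_limit
  if (hf_cutoff < es$rate / 2) {
    kernel <- .fir_kernel(es$rate, hf_cutoff, "high", 10)
    hf <- vapply(es$epochs, function(ep) .epoch_ptp(.apply_fir(ep, kernel)),
                 numeric(1))
    bad_hf <- hf > hf_limit
  } else {
    warning("hf_cutoff at or above Nyquist; high-frequency criterion skipped")
    bad_hf <- rep(FALSE, n)
  }
  reason <- ifelse(bad_ptp & bad_hf, "ptp+hf",
                   ifelse(bad_ptp, "ptp", ifelse(bad_hf, "hf", "")))
  keep <- !(bad_ptp | bad_hf)
  if (!any(keep))
    abort_data(sprintf("all %d epochs rejected (ptp: %d, hf: %d)",
                       n, sum(bad_ptp), sum(bad_hf)))
  log <- data.frame(epoch_index = seq_len(n), kept = keep, reason = reason,
                    stringsAsFactors = FALSE)
  epoch_set(es$epochs[keep], es$rate, es$epoch_duration, log)
}

#' Trim clean epochs to a fixed analysis length
#'
#' Keeps the first `k` epochs where `k` is the smallest count whose total
#' duration reaches `target` seconds (25 epochs of 10.24 s for the default
#' 250 s), so every subject contributes the same amount of data.
#'
#' @param es an [epoch_set()].
#' @param target minimum total duration in seconds (default 250).
#' @return A trimmed [epoch_set()].
#' @export
trim_to_duration <- function(es, target = 250) {
  stopifnot(inherits(es, "epoch_set"))
  k <- ceiling(target / es$epoch_duration)
  if (length(es$epochs) < k)
    abort_data(sprintf("insufficient clean data: %.2f s available, %g s required",
                       length(es$epochs) * es$epoch_duration, target))
  epoch_set(es$epochs[seq_len(k)], es$rate, es$epoch_duration,
            es$rejection_log)
}
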