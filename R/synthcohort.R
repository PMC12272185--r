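#' Synthetic cohort specification
#'
#' Parameters of the planted age effects. Defaults encode the lifespan
#' pattern the analysis is built to detect: low-frequency (delta/theta)
#' source amplitudes decline monotonically with age while beta/gamma
#' amplitudes increase, envelope coupling carries band-specific age trends,
#' field spread mixes sources instantaneously into sensors, and white sensor
#' noise is added.
#'
#' @param n_subjects cohort size (>= 2).
#' @param age_low,age_high age range in years (default 18-83).
#' @param band_effects data frame `band`, `baseline`, `slope` giving each
#'   band's source amplitude (arbitrary units) at the age midpoint and its
#'   change per year.
#' @param coupling_effects data frame `band`, `node_i`, `node_j`, `rho0`,
#'   `slope`: planted envelope correlation at the age midpoint and its
#'   change per year.
#' @param sensor_noise_sd additive white sensor noise SD, fT.
#' @param subject_sd SD (years) of the shared subject-level deviation of
#'   "functional age" from chronological age; the default 5*sqrt(pi/2)
#'   makes the best attainable mean absolute prediction error 5 years.
#' @param feature_noise_sd SD of independent per-feature noise in
#'   [simulate_feature_cohort()].
#' @param age_sampling `"uniform"` or `"bimodal"` (sparse middle age).
#' @param mixing logical; instantaneous field-spread mixing of sources.
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100, age_low = 18, age_high = 83,
                        band_effects = NULL, coupling_effects = NULL,
                        sensor_noise_sd = 50, subject_sd = 5 * sqrt(pi / 2),
                        feature_noise_sd = 0.5,
                        age_sampling = c("uniform", "bimodal"),
                        mixing = TRUE, seed = 1L) {
  if (n_subjects < 2L) abort_config("n_subjects must be at least 2")
  if (age_low >= age_high) abort_config("age_low must be below age_high")
  if (is.null(band_effects))
    band_effects <- data.frame(
      band = c("delta", "theta", "alpha", "beta", "gamma"),
      baseline = c(1.0, 1.0, 1.2, 0.8, 0.6),
      slope = c(-0.006, -0.005, -0.002, 0.006, 0.005),
      stringsAsFactors = FALSE)
  if (is.null(coupling_effects))
    coupling_effects <- data.frame(
      band = c("alpha", "beta"), node_i = c(1L, 1L), node_j = c(2L, 2L),
      rho0 = c(0.5, 0.3), slope = c(-0.004, 0.003),
      stringsAsFactors = FALSE)
  if (any(abs(coupling_effects$rho0) >= 1))
    abort_config("baseline coupling rho must lie in (-1, 1)")
  structure(list(n_subjects = as.integer(n_subjects), age_low = age_low,
                 age_high = age_high, band_effects = band_effects,
                 coupling_effects = coupling_effects,
                 sensor_noise_sd = sensor_noise_sd, subject_sd = subject_sd,
                 feature_noise_sd = feature_noise_sd,
                 age_sampling = match.arg(age_sampling),
                 mixing = isTRUE(mixing), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample cohort ages
#'
#' Uniform over the spec's range by default; the bimodal option thins the
#' middle of the range (mimicking cohorts with sparse coverage of middle
#' age) by mixing two triangular humps at the ends.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (defaults to the spec's).
#' @return Numeric vector of ages in years.
#' @export
sample_ages <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    n <- spec$n_subjects
    if (spec$age_sampling == "uniform") {
      stats::runif(n, spec$age_low, spec$age_high)
    } else {
      lo <- spec$age_low; hi <- spec$age_high; span <- hi - lo
      side <- stats::runif(n) < 0.5
      u <- stats::rbeta(n, 1.6, 4)
      ifelse(side, lo + u * span, hi - u * span)
    }
  })
}

# Unit-SD band-limited Gaussian noise (FIR-filtered white noise).
.band_noise <- function(n, rate, low, high) {
  tw <- min(.transition_bw(low), .transition_bw(high))
  kernel <- .fir_kernel(rate, c(low, high), "pass", tw)
  x <- .apply_fir(matrix(stats::rnorm(n), 1), kernel)[1, ]
  x / stats::sd(x)
}

# Unit-SD 1/f (pink) background noise via spectral shaping.
.pink_noise <- function(n, rate) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                        # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Simulate one subject's sensor recording
#'
#' Each dipolar source emits band-limited Gaussian noise whose amplitude is
#' the band's baseline plus slope x (age - cohort midpoint), superposed on a
#' 1/f background; negative planted amplitudes are clipped to zero with a
#' warning. Sensor data are the lead-field projections of all sources plus
#' white noise.
#'
#' @param spec a [cohort_spec()].
#' @param age subject age, years.
#' @param sources list of [dipole_spec()].
#' @param leadfields list of [sphere_lead_field()], one per source.
#' @param array the [sensor_array()].
#' @param duration recording length, seconds (>= 1).
#' @param rate sampling rate, Hz.
#' @param seed integer seed.
#' @param source_bands character vector assigning each source a band of the
#'   spec's `band_effects` (recycled).
#' @param background_scale relative amplitude of the 1/f background.
#' @return A [sensor_recording()]; the planted source time courses are
#'   attached as attribute `"sources"`.
#' @export
simulate_subject_sensors <- function(spec, age, sources, leadfields, array,
                                     duration = 250, rate = 300,
                                     seed = spec$seed,
                                     source_bands = NULL,
                                     background_scale = 0.2) {
  if (length(sources) != length(leadfields))
    abort_shape("need one lead field per source")
  if (duration < 1) abort_config("duration must be at least 1 s")
  m <- nrow(array$positions)
  for (lf in leadfields)
    if (nrow(lf$gains) != m) abort_shape("lead field channel count mismatch")
  be <- spec$band_effects
  if (is.null(source_bands))
    source_bands <- rep(be$band, length.out = length(sources))
  mid <- (spec$age_low + spec$age_high) / 2
  n <- round(duration * rate)
  with_seed(seed, {
    S <- matrix(0, length(sources), n)
    for (i in seq_along(sources)) {
      row <- match(source_bands[i], be$band)
      if (is.na(row)) abort_config(sprintf("unknown band '%s'", source_bands[i]))
      amp <- be$baseline[row] + be$slope[row] * (age - mid)
      if (amp < 0) {
        warning(sprintf("planted amplitude for band %s clipped to zero at age %.1f",
                        source_bands[i], age))
        amp <- 0
      }
      edges <- .band_edges(source_bands[i])
      bl <- .band_noise(n, rate, edges[1], edges[2])
      S[i, ] <- sources[[i]]$moment_scale *
        (amp * bl + background_scale * .pink_noise(n, rate))
    }
    B <- matrix(0, m, n)
    for (i in seq_along(sources)) {
      h <- leadfields[[i]]$gains %*% sources[[i]]$orientation
      B <- B + h %*% S[i, , drop = FALSE]
    }
    if (spec$sensor_noise_sd > 0)
      B <- B + matrix(stats::rnorm(m * n, sd = spec$sensor_noise_sd), m, n)
    rec <- sensor_recording(B, rate, array$names)
    attr(rec, "sources") <- S
    rec
  })
}

.band_edges <- function(band) {
  sch <- band_scheme()
  i <- match(band, sch$name)
  if (is.na(i)) abort_config(sprintf("unknown band '%s'", band))
  c(sch$low[i], sch$high[i])
}

#' Plant a pair of envelope-coupled band-limited sources
#'
#' Generates two band-limited carriers with independent phases (so their
#' zero-lag raw correlation is near zero) whose amplitude envelopes share a
#' slow log-normal modulator. The sharing weight is solved numerically
#' (bisection on the realised envelopes, measured after 1 Hz block-mean
#' downsampling — the rate at which connectivity is computed) so the
#' envelope correlation hits the target `rho`.
#'
#' @param band band name from [band_scheme()], or `c(low, high)` in Hz.
#' @param rho target envelope correlation, |rho| < 1.
#' @param duration seconds.
#' @param rate Hz.
#' @param seed integer seed.
#' @param mod_sd log-amplitude SD of the shared modulator.
#' @return A 2 x samples matrix of source time courses (unit SD rows).
#' @export
plant_coupled_sources <- function(band = "alpha", rho = 0.6, duration = 250,
                                  rate = 300, seed = 1L, mod_sd = 1.25) {
  if (abs(rho) >= 1) abort_config("|rho| must be below 1")
  edges <- if (is.character(band)) .band_edges(band) else as.numeric(band)
  n <- round(duration * rate)
  with_seed(seed, {
    carriers <- rbind(.band_noise(n, rate, edges[1], edges[2]),
                      .band_noise(n, rate, edges[1], edges[2]))
    # slow modulators, 0.05-0.3 Hz
    mods <- rbind(.band_noise(n, rate, 0.05, 0.3),
                  .band_noise(n, rate, 0.05, 0.3),
                  .band_noise(n, rate, 0.05, 0.3))
    mix <- function(w) {
      a1 <- exp(mod_sd * (abs(w) * mods[1, ] + sqrt(1 - w^2) * mods[2, ]))
      a2 <- exp(mod_sd * (sign(w) * abs(w) * mods[1, ] + sqrt(1 - w^2) * mods[3, ]))
      rbind(a1 * carriers[1, ], a2 * carriers[2, ])
    }
    env_cor <- function(S) {
      e <- apply(S, 1, function(x)
        downsample_envelope(hilbert_envelope(x), rate, 1))
      stats::cor(e[, 1], e[, 2])
    }
    f <- function(w) env_cor(mix(w)) - rho
    w <- if (abs(rho) < 1e-12) 0 else {
      lo <- if (rho > 0) 0 else -0.999
      hi <- if (rho > 0) 0.999 else 0
      flo <- f(lo); fhi <- f(hi)
      if (flo * fhi > 0) {
        warning("target envelope correlation outside achievable range; using extreme")
        if (abs(flo) < abs(fhi)) lo else hi
      } else stats::uniroot(f, c(lo, hi), tol = 1e-3)$root
    }
    S <- mix(w)
    S / apply(S, 1, stats::sd)
  })
}

#' Simulate a feature-level cohort
#'
#' A shortcut past the signal chain: per-subject band-power features and AEC
#' tensors carrying planted linear age trends, so the inference and
#' regression stages can be exercised directly. Each subject has a
#' "functional age" `age + N(0, subject_sd)` shared across features (the
#' component that bounds achievable prediction accuracy), and every feature
#' adds independent Gaussian noise. Power feature for node i, band b:
#' `baseline_b + slope_b * scale_i * (functional age - midpoint) + noise`.
#' AEC entries are planted on the Fisher-z scale and back-transformed, so
#' matrices are symmetric with zero diagonal and entries in (-1, 1).
#'
#' @param spec a [cohort_spec()].
#' @param n_regions number of nodes (>= 1).
#' @param seed integer seed.
#' @return List with elements `power` (data frame, subject_id +
#'   region-by-band columns), `aec` (4-d array subject x band x node x
#'   node), `metadata` (data frame subject_id, age, sex, cohort), and
#'   `functional_age` (the latent used to generate the features).
#' @export
simulate_feature_cohort <- function(spec, n_regions = 78, seed = spec$seed) {
  if (n_regions < 1L) abort_config("n_regions must be at least 1")
  be <- spec$band_effects
  mid <- (spec$age_low + spec$age_high) / 2
  with_seed(seed, {
    n <- spec$n_subjects
    ages <- sample_ages(spec, seed = stats::runif(1, 1, 2^30))
    sex <- sample(c(0L, 1L), n, replace = TRUE)
    fage <- ages + stats::rnorm(n, sd = spec$subject_sd)
    # smooth deterministic per-region effect scaling in [0.5, 1.5]
    rscale <- 1 + 0.5 * sin(seq(0, 2 * pi, length.out = n_regions + 1)[-1])
    nodes <- sprintf("node%03d", seq_len(n_regions))
    cols <- as.vector(t(outer(nodes, be$band, paste, sep = "_")))
    Xp <- matrix(0, n, n_regions * nrow(be))
    k <- 1L
    for (r in seq_len(n_regions)) for (b in seq_len(nrow(be))) {
      Xp[, k] <- be$baseline[b] + be$slope[b] * rscale[r] * (fage - mid) +
        stats::rnorm(n, sd = spec$feature_noise_sd * abs(be$slope[b]) * 20)
      k <- k + 1L
    }
    colnames(Xp) <- cols
    aec <- array(0, dim = c(n, nrow(be), n_regions, n_regions),
                 dimnames = list(NULL, be$band, nodes, nodes))
    ce <- spec$coupling_effects
    for (s in seq_len(n)) {
      for (b in seq_len(nrow(be))) {
        Z <- matrix(0, n_regions, n_regions)
        base_z <- atanh(0.1)
        upper <- upper.tri(Z)
        Z[upper] <- base_z + stats::rnorm(sum(upper),
                                          sd = 0.05 * (spec$feature_noise_sd > 0))
        for (ci in seq_len(nrow(ce))) {
          if (ce$band[ci] != be$band[b]) next
          i <- ce$node_i[ci]; j <- ce$node_j[ci]
          if (i > n_regions || j > n_regions) next
          z <- atanh(ce$rho0[ci]) + ce$slope[ci] * (fage[s] - mid)
          Z[min(i, j), max(i, j)] <- z +
            stats::rnorm(1, sd = 0.05 * (spec$feature_noise_sd > 0))
        }
        Z <- Z + t(Z)
        R <- tanh(Z)
        diag(R) <- 0
        aec[s, b, , ] <- R
      }
    }
    ids <- sprintf("sub%04d", seq_len(n))
    power <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
                   as.data.frame(Xp))
    metadata <- data.frame(subject_id = ids, age = ages, sex = sex,
                           cohort = "synthetic", stringsAsFactors = FALSE)
    list(power = power, aec = aec, metadata = metadata, functional_age = fage)
  })
}
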