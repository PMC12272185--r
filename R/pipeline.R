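#' Pipeline configuration
#'
#' A flat named list of every stage parameter with the pipeline defaults:
#' 1-150 Hz band-pass, 50/60 Hz notches, 300 Hz rate, 10.24 s epochs,
#' 6000 fT peak-to-peak and 2000 fT >110 Hz rejection limits, 250 s
#' analysis length, 5% Tikhonov fraction, Welch segments of 4096 samples,
#' 1 Hz envelope rate, and the cross-validation defaults. Serialisable to a
#' flat `key = value` text file; unknown keys are rejected on read.
#'
#' @param ... overrides of the default keys.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L, n_subjects = 20L, n_channels = 30L, n_sources = 5L,
    duration = 260, rate = 300,
    bp_low = 1, bp_high = 149, notch_freqs = c(50, 60),
    epoch_duration = 10.24, ptp_limit = 6000, hf_limit = 2000,
    hf_cutoff = 110, trim_target = 250,
    reg_fraction = 0.05, nai = TRUE,
    n_fft = 4096, env_rate = 1, edge_trim = 2,
    n_perm = 200L, n_boot = 200L,
    cv_k = 2L, cv_repeats = 2L,
    cv_bin_limits = c(0, 22.5, 45, 67.5, 90),
    run_pls = TRUE, run_brainage = TRUE,
    sensor_noise_sd = 50)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    abort_config("unknown configuration key(s): " %+%
                   paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path text file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  defaults <- pipeline_config()
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  overrides <- list()
  for (pair in kv) {
    if (length(pair) != 2) abort_config("malformed config line: " %+% pair[1])
    key <- trimws(pair[1])
    if (!key %in% names(defaults))
      abort_config("unknown configuration key(s): " %+% key)
    raw <- strsplit(trimws(pair[2]), ",")[[1]]
    proto <- defaults[[key]]
    overrides[[key]] <- if (is.logical(proto)) as.logical(raw)
      else if (is.integer(proto)) as.integer(raw)
      else if (is.numeric(proto)) as.numeric(raw)
      else raw
  }
  do.call(pipeline_config, overrides)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> preprocess -> source reconstruction -> spectral
#' and connectivity features -> PLS and brain-age stages in order, writing
#' every table under `out_dir` and emitting a run manifest (timestamp,
#' config hash, per-stage seeds, output checksums). Deterministic for a
#' fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = stage_seed(config$seed, "simulate"),
                pls = stage_seed(config$seed, "pls"),
                brainage = stage_seed(config$seed, "brainage"))
  scheme <- band_scheme()
  array <- make_sensor_array(config$n_channels, seed = seeds$simulate)
  # fixed tangential sources on a shallow shell
  src_pos <- lapply(seq_len(config$n_sources), function(i) {
    ang <- 2 * pi * i / config$n_sources
    c(0.05 * cos(ang), 0.05 * sin(ang), 0.04)
  })
  sources <- lapply(src_pos, function(p) {
    tang <- c(-p[2], p[1], 0); tang <- tang / vnorm(tang)
    dipole_spec(p, tang, moment_scale = 30)
  })
  lfs <- lapply(seq_along(src_pos), function(i)
    sphere_lead_field(src_pos[[i]], array, source_id = sprintf("node%03d", i)))

  spec <- cohort_spec(n_subjects = config$n_subjects,
                      sensor_noise_sd = config$sensor_noise_sd,
                      seed = seeds$simulate)
  ages <- sample_ages(spec)
  ids <- sprintf("sub%04d", seq_len(config$n_subjects))

  stcs <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    rec <- simulate_subject_sensors(spec, ages[s], sources, lfs, array,
                                    duration = config$duration,
                                    rate = config$rate,
                                    seed = seeds$simulate + s)
    rec <- fir_bandpass(rec, config$bp_low, config$bp_high)
    rec <- notch(rec, config$notch_freqs)
    es <- epoch(rec, config$epoch_duration)
    es <- reject_epochs(es, config$ptp_limit, config$hf_limit, config$hf_cutoff)
    es <- trim_to_duration(es, config$trim_target)
    C <- tikhonov_regularise(data_covariance(es), config$reg_fraction)
    wts <- lapply(lfs, function(lf) lcmv_scalar_weights(C, lf))
    stcs[[s]] <- apply_weights(es, wts, nai = config$nai, subject_id = ids[s])
  }

  power <- cohort_band_power(stcs, scheme, n_fft = config$n_fft)
  write_band_power_csv(power, file.path(out_dir, "band_power.csv"))
  metadata <- data.frame(subject_id = ids, age = ages,
                         sex = rep(c(0L, 1L), length.out = config$n_subjects),
                         cohort = "synthetic", stringsAsFactors = FALSE)
  write_metadata_csv(metadata, file.path(out_dir, "metadata.csv"))

  aec_first <- cohort_aec(stcs[[1]], scheme, env_rate = config$env_rate,
                          edge_trim = config$edge_trim)
  utils::write.csv(do.call(rbind, lapply(aec_first, aec_to_long)),
                   file.path(out_dir, "aec_subject1_long.csv"),
                   row.names = FALSE)

  outputs <- c("band_power.csv", "metadata.csv", "aec_subject1_long.csv")

  if (isTRUE(config$run_pls)) {
    Xmat <- as.matrix(power[, -1, drop = FALSE])
    fit <- meg_pls(Xmat, cbind(age = ages), n_perm = config$n_perm,
                   n_boot = config$n_boot, seed = seeds$pls)
    comp <- data.frame(component = seq_along(fit$singular_values),
                       singular_value = fit$singular_values,
                       explained_covariance = fit$explained_covariance,
                       p_value = fit$p_values)
    utils::write.csv(comp, file.path(out_dir, "pls_components.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "pls_components.csv")
  }
  if (isTRUE(config$run_brainage)) {
    ba <- brain_age(as.matrix(power[, -1, drop = FALSE]), ages,
                    scheme = cv_scheme(config$cv_k, config$cv_repeats,
                                       config$cv_bin_limits,
                                       seed = seeds$brainage))
    utils::write.csv(ba$subjects, file.path(out_dir, "brainage_subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(ba$folds, file.path(out_dir, "brainage_folds.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "brainage_subjects.csv", "brainage_folds.csv")
  }

  cfg_path <- file.path(out_dir, "config.txt")
  write_config(config, cfg_path)
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("oscillage")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seeds = seeds,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
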