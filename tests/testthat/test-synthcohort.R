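test_that("cohort spec validates its invariants and ages stay in range", {
  expect_error(cohort_spec(n_subjects = 1), class = "oscillage_config_error")
  expect_error(cohort_spec(age_low = 50, age_high = 40),
               class = "oscillage_config_error")
  spec <- cohort_spec(n_subjects = 500, seed = 7)
  ages <- sample_ages(spec)
  expect_true(all(ages >= 18 & ages <= 83))
  expect_identical(ages, sample_ages(spec))
  bi <- cohort_spec(n_subjects = 2000, age_sampling = "bimodal", seed = 7)
  ages_bi <- sample_ages(bi)
  mid_frac <- mean(ages_bi > 40 & ages_bi < 60)
  expect_lt(mid_frac, mean(ages_bi <= 40))       # sparse middle
})

test_that("a single noiseless source gives rank-1 sensor data", {
  arr <- make_sensor_array(10, seed = 1)
  spec <- cohort_spec(n_subjects = 5, sensor_noise_sd = 0, seed = 2)
  pos <- c(0.04, 0, 0.03)
  dp <- dipole_spec(pos, c(0, 1, 0), moment_scale = 10)
  lf <- sphere_lead_field(pos, arr)
  rec <- simulate_subject_sensors(spec, age = 50, list(dp), list(lf), arr,
                                  duration = 5, seed = 3)
  sv <- svd(rec$data)$d
  expect_lt(sv[2] / sv[1], 1e-10)
  # determinism
  rec2 <- simulate_subject_sensors(spec, age = 50, list(dp), list(lf), arr,
                                   duration = 5, seed = 3)
  expect_identical(rec$data, rec2$data)
})

test_that("planted negative delta slope shows up in sensor delta power vs age", {
  arr <- make_sensor_array(8, seed = 1)
  pos <- c(0.04, 0.01, 0.03)
  dp <- dipole_spec(pos, c(-0.01, 0.04, 0) / sqrt(0.04^2 + 0.01^2),
                    moment_scale = 20)
  lf <- sphere_lead_field(pos, arr)
  signs <- vapply(1:10, function(s) {
    spec <- cohort_spec(n_subjects = 30, sensor_noise_sd = 5, seed = s)
    ages <- sample_ages(spec)
    dp_pow <- vapply(seq_along(ages), function(i) {
      rec <- simulate_subject_sensors(spec, ages[i], list(dp), list(lf), arr,
                                      duration = 8, seed = s * 1000 + i,
                                      source_bands = "delta")
      # direct periodogram oracle on the strongest channel
      ch <- which.max(rowSums(lf$gains^2))
      oracle_band_power(rec$data[ch, ], 300, 1, 3)
    }, numeric(1))
    sign(stats::coef(stats::lm(dp_pow ~ ages))[2])
  }, numeric(1))
  expect_gte(sum(signs == -1), 9)
})

test_that("planted envelope coupling hits its target and stays uncorrelated at zero lag", {
  # rho = 0.9 sits at the generator's achievable ceiling; when a realisation
  # falls short the generator warns and uses the closest attainable mixing
  hits <- vapply(1:20, function(s) {
    S <- suppressWarnings(
      plant_coupled_sources("alpha", rho = 0.9, duration = 250, rate = 300,
                            seed = s))
    e1 <- downsample_envelope(hilbert_envelope(S[1, ]), 300, 1)
    e2 <- downsample_envelope(hilbert_envelope(S[2, ]), 300, 1)
    stats::cor(e1, e2)
  }, numeric(1))
  expect_gte(sum(hits >= 0.75 & hits <= 0.98), 18)
  S0 <- plant_coupled_sources("alpha", rho = 0, duration = 250, rate = 300,
                              seed = 1)
  e1 <- downsample_envelope(hilbert_envelope(S0[1, ]), 300, 1)
  e2 <- downsample_envelope(hilbert_envelope(S0[2, ]), 300, 1)
  expect_lt(abs(stats::cor(e1, e2)), 0.1)
  expect_lt(abs(stats::cor(S0[1, ], S0[2, ])), 0.2)
  expect_equal(ncol(S0), 75000)               # 250 s at 300 Hz
  expect_error(plant_coupled_sources("nosuch", 0.5),
               class = "oscillage_config_error")
})

test_that("feature cohorts carry recoverable planted age trends", {
  # noiseless: every feature is an exact affine function of age
  spec0 <- cohort_spec(n_subjects = 40, subject_sd = 0, feature_noise_sd = 0,
                       seed = 4)
  fc0 <- simulate_feature_cohort(spec0, n_regions = 3, seed = 4)
  X0 <- as.matrix(fc0$power[, -1])
  for (j in c(1, 7, 15)) {
    fit <- stats::lm(X0[, j] ~ fc0$metadata$age)
    expect_lt(max(abs(stats::residuals(fit))), 1e-9)
  }
  # shape: 78 regions x 5 bands = 390 columns
  spec <- cohort_spec(n_subjects = 50, seed = 5)
  fc <- simulate_feature_cohort(spec, n_regions = 78, seed = 5)
  expect_equal(ncol(fc$power) - 1, 390)
  # OLS recovers the planted slopes within 3 standard errors almost always
  be <- spec$band_effects
  rscale <- 1 + 0.5 * sin(seq(0, 2 * pi, length.out = 11)[-1])
  bigspec <- cohort_spec(n_subjects = 400, subject_sd = 0, seed = 6)
  bigfc <- simulate_feature_cohort(bigspec, n_regions = 10, seed = 6)
  Xb <- as.matrix(bigfc$power[, -1])
  ok <- 0; tot <- 0
  k <- 1
  for (r in 1:10) for (b in 1:5) {
    fit <- summary(stats::lm(Xb[, k] ~ bigfc$metadata$age))
    est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
    truth <- be$slope[b] * rscale[r]
    ok <- ok + (abs(est - truth) <= 3 * se); tot <- tot + 1
    k <- k + 1
  }
  expect_gte(ok / tot, 0.95)
})

test_that("AEC tensors are symmetric, zero-diagonal, bounded and deterministic", {
  spec <- cohort_spec(n_subjects = 6, seed = 8)
  fc <- simulate_feature_cohort(spec, n_regions = 5, seed = 8)
  expect_equal(dim(fc$aec), c(6, 5, 5, 5))
  for (s in 1:6) for (b in 1:5) {
    M <- fc$aec[s, b, , ]
    expect_equal(M, t(M))
    expect_equal(diag(M), rep(0, 5), ignore_attr = TRUE)
    expect_true(all(M > -1 & M < 1))
  }
  fc2 <- simulate_feature_cohort(spec, n_regions = 5, seed = 8)
  expect_identical(fc, fc2)
})
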