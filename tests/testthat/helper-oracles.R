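# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation in R/.

# Sarvas single-sphere field, re-derived independently: builds the field
# vector from explicitly named scalar sub-terms and loops over moments
# rather than vectorising, and takes the conductor centre as origin.
oracle_sarvas_gain <- function(dipole_pos, sensor_pos, sensor_ori,
                               center = c(0, 0, 0)) {
  q_unit <- diag(3)
  r0 <- dipole_pos - center
  out <- matrix(NA_real_, nrow(sensor_pos), 3)
  for (i in seq_len(nrow(sensor_pos))) {
    r <- sensor_pos[i, ] - center
    a_vec <- r - r0
    a <- sqrt(sum(a_vec * a_vec))
    rmag <- sqrt(sum(r * r))
    F_s <- a * (rmag * a + rmag^2 - sum(r0 * r))
    adotr <- sum(a_vec * r)
    nabla_F <- (a^2 / rmag + adotr / a + 2 * a + 2 * rmag) * r -
      (a + 2 * rmag + adotr / a) * r0
    for (j in 1:3) {
      q <- q_unit[j, ]
      Q <- crossprod_3(q, r0)
      B <- (1e-7 / F_s^2) * (F_s * Q - sum(Q * r) * nabla_F)
      # 1 nA.m moment, tesla -> fT
      out[i, j] <- sum(B * sensor_ori[i, ]) * 1e-9 * 1e15
    }
  }
  out
}

crossprod_3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Radial sensor reading of a current dipole in ANY spherically symmetric
# conductor equals the radial component of the free-space (infinite medium)
# dipole field -- a closed form independent of the Sarvas expression.
oracle_radial_field <- function(dipole_pos, moment, sensor_pos,
                                center = c(0, 0, 0)) {
  r0 <- dipole_pos - center
  vapply(seq_len(nrow(sensor_pos)), function(i) {
    r <- sensor_pos[i, ] - center
    d <- r - r0
    B <- 1e-7 * crossprod_3(moment, d) / sum(d * d)^1.5
    sum(B * r) / sqrt(sum(r * r)) * 1e-9 * 1e15
  }, numeric(1))
}

# Closed-form two-signal Loewdin orthogonalisation (symmetric whitening of
# the 2 x 2 correlation structure).
oracle_lowdin_2 <- function(X) {
  A <- t(X - rowMeans(X))
  S <- crossprod(A)
  e <- eigen(S, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  t(A %*% W)
}

# Exhaustive Mann-Whitney oracle: enumerates every assignment of the pooled
# VALUES to groups and computes U by directly counting pairwise wins.
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  count_u <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- count_u(x, y)
  center <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, function(idx) count_u(pooled[idx], pooled[-idx]))
  list(U = u_obs,
       p = mean(abs(us - center) >= abs(u_obs - center) - 1e-9))
}

# Random unit-gain spatial filters for the minimum-variance check.
oracle_random_unit_gain <- function(h, n = 10000) {
  m <- length(h)
  W0 <- matrix(stats::rnorm(m * n), n)
  corr <- (1 - W0 %*% h) / sum(h * h)
  W0 + corr %*% t(h)
}

# Periodogram band power (plain rectangular-window, no Welch machinery).
oracle_band_power <- function(x, rate, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * rate / n
  sum(p[f >= low & f <= high])
}

rand_spd <- function(m) {
  A <- matrix(stats::rnorm(m * m), m)
  crossprod(A) + diag(m) * 0.05
}
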