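#' Sensor array constructor
#'
#' Bundles magnetometer positions, sensitive-axis orientations and channel
#' names into a validated `sensor_array` object. Positions are head-centred
#' cartesian coordinates in metres; each orientation must be a unit vector.
#'
#' @param positions numeric matrix, channels x 3, metres.
#' @param orientations numeric matrix, channels x 3, unit vectors.
#' @param names character vector of channel labels.
#' @param conductor_radius radius (m) of the spherical conductor the array
#'   surrounds; every sensor must lie strictly outside it.
#' @return An object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations, names = NULL,
                         conductor_radius = 0.09) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L)
    abort_shape("positions and orientations must have 3 columns")
  m <- nrow(positions)
  if (m < 1L) abort_geometry("sensor array needs at least one channel")
  if (nrow(orientations) != m)
    abort_shape("positions and orientations disagree on channel count")
  on <- sqrt(rowSums(orientations^2))
  if (any(abs(on - 1) > 1e-12))
    abort_geometry("sensor orientations must have unit norm (within 1e-12)")
  r <- sqrt(rowSums(positions^2))
  if (any(r <= conductor_radius))
    abort_geometry("all sensors must lie strictly outside the conductor sphere")
  if (is.null(names)) names <- sprintf("MEG%03d", seq_len(m))
  structure(list(positions = positions, orientations = orientations,
                 names = as.character(names),
                 conductor_radius = conductor_radius),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d point magnetometers, conductor radius %.3f m\n",
              nrow(x$positions), x$conductor_radius))
  invisible(x)
}

#' Quasi-uniform hemispheric magnetometer array
#'
#' Builds a deterministic helmet-like fixture: radially oriented point
#' magnetometers placed on the upper hemisphere of a sphere of the given
#' radius using a golden-angle spiral. The seed fixes the azimuthal phase of
#' the spiral so distinct seeds give rotated but equally uniform layouts.
#'
#' @param n_channels number of magnetometers (>= 4).
#' @param radius helmet radius in metres; must exceed `conductor_radius`.
#' @param seed integer controlling the azimuthal phase.
#' @param conductor_radius conductor sphere radius in metres.
#' @return A [sensor_array()].
#' @export
make_sensor_array <- function(n_channels, radius = 0.12, seed = 1L,
                              conductor_radius = 0.09) {
  if (n_channels < 4L) abort_config("n_channels must be at least 4")
  if (radius <= conductor_radius)
    abort_geometry("helmet radius must exceed the conductor radius")
  i <- seq_len(n_channels)
  # z spans the upper hemisphere, kept off the equator so sensors sit above
  # the head the way a helmet does
  z <- 0.15 + (0.995 - 0.15) * (i - 0.5) / n_channels
  golden <- pi * (3 - sqrt(5))
  phase <- 2 * pi * ((as.numeric(seed) * 0.6180339887) %% 1)
  phi <- i * golden + phase
  s <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(s * cos(phi), s * sin(phi), z)
  ori <- pos / radius   # radial orientation
  sensor_array(pos, ori, sprintf("MEG%03d", i),
               conductor_radius = conductor_radius)
}

# Sarvas closed-form magnetic field of a current dipole in a homogeneous
# conducting sphere, evaluated at external points and projected on the
# sensors' sensitive axes. Returns fT per nA.m of dipole moment.
.sarvas_gain <- function(dipole_position, array, sphere_center) {
  r0 <- as.numeric(dipole_position) - as.numeric(sphere_center)
  P <- sweep(array$positions, 2, as.numeric(sphere_center))
  O <- array$orientations
  m <- nrow(P)
  gains <- matrix(0, m, 3)
  # 1 nA.m moment expressed in A.m, field in T scaled to fT
  scale <- 1e-7 * 1e-9 * 1e15   # mu0/4pi * nA.m * T->fT
  for (ch in seq_len(m)) {
    r <- P[ch, ]
    rn <- vnorm(r)
    a <- r - r0
    an <- vnorm(a)
    if (an < 1e-12) abort_geometry("sensor coincident with the dipole")
    ar <- sum(a * r)
    F <- an * (rn * an + rn^2 - sum(r0 * r))
    if (abs(F) < 1e-30) abort_geometry("singular geometry for Sarvas formula")
    gF <- (an^2 / rn + ar / an + 2 * an + 2 * rn) * r -
      (an + 2 * rn + ar / an) * r0
    for (k in 1:3) {
      q <- c(0, 0, 0); q[k] <- 1
      qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
                q[3] * r0[1] - q[1] * r0[3],
                q[1] * r0[2] - q[2] * r0[1])
      B <- scale / F^2 * (F * qxr0 - sum(qxr0 * r) * gF)
      gains[ch, k] <- sum(B * O[ch, ])
    }
  }
  gains
}

#' Spherical-conductor magnetic lead field
#'
#' Computes the channels x 3 gain matrix of a current dipole inside a
#' homogeneous conducting sphere using the Sarvas closed form. Column j holds
#' the sensor readings (fT) produced by a unit (1 nA.m) dipole along the j-th
#' cartesian axis; the field of an arbitrary moment is `gains %*% moment`.
#' Gains depend only on geometry relative to `sphere_center`; radially
#' oriented dipoles are magnetically silent.
#'
#' @param dipole_position 3-vector, metres, strictly inside the conductor.
#' @param array a [sensor_array()].
#' @param sphere_center 3-vector, metres.
#' @return An object of class `lead_field` with fields `gains` (channels x 3,
#'   fT per nA.m), `source_id` and `channel_names`.
#' @param source_id label stored with the result.
#' @export
sphere_lead_field <- function(dipole_position, array,
                              sphere_center = c(0, 0, 0),
                              source_id = "src") {
  stopifnot(inherits(array, "sensor_array"))
  dipole_position <- as.numeric(dipole_position)
  if (length(dipole_position) != 3L) abort_shape("dipole position must be a 3-vector")
  if (vnorm(dipole_position - as.numeric(sphere_center)) >= array$conductor_radius)
    abort_geometry("dipole must lie strictly inside the conductor sphere")
  gains <- .sarvas_gain(dipole_position, array, sphere_center)
  if (!all(is.finite(gains))) abort_numeric("non-finite lead field entries")
  structure(list(gains = gains, source_id = source_id,
                 channel_names = array$names,
                 position = dipole_position),
            class = "lead_field")
}

#' Dipole specification
#'
#' @param position 3-vector, metres, inside the conductor.
#' @param orientation unit 3-vector (tangential orientations are visible to
#'   MEG; the radial component is silent in a sphere).
#' @param moment_scale source amplitude in nA.m-equivalent units.
#' @return An object of class `dipole_spec`.
#' @export
dipole_spec <- function(position, orientation, moment_scale = 1) {
  position <- as.numeric(position); orientation <- as.numeric(orientation)
  if (length(position) != 3L || length(orientation) != 3L)
    abort_shape("position and orientation must be 3-vectors")
  n <- vnorm(orientation)
  if (abs(n - 1) > 1e-9) orientation <- orientation / n
  structure(list(position = position, orientation = orientation,
                 moment_scale = moment_scale), class = "dipole_spec")
}
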