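#' Sensor arrays and analytic spherical-conductor leadfields
#'
#' The forward model maps source dipole amplitudes to sensor measurements.
#' Here the head is a spherically symmetric conductor, for which the
#' magnetic field of a current dipole has the closed-form Sarvas solution;
#' radially oriented dipoles are magnetically silent.  Leadfield columns are
#' expressed in T/(A*m) so that a unit source amplitude of 1 A*m maps
#' directly to sensor-space field values.
#'
#' @name forward_model
#' @keywords internal
NULL

MU0_OVER_4PI <- 1e-7  # vacuum permeability / 4 pi, T*m/A

#' Build a helmet-like magnetometer array
#'
#' Distributes `n` radial magnetometers quasi-uniformly (Fibonacci lattice)
#' over the portion of a sphere of radius `radius` with `z > z_min`,
#' emulating a sensor helmet that covers the top and sides of the head.
#'
#' @param n Number of sensors.
#' @param radius Helmet radius in mm (sensors must lie outside all sources).
#' @param z_min Lower z cut of the helmet cap, mm.
#' @return A `sensor_array`: list with `positions` (n x 3, mm),
#'   `orientations` (n x 3 unit vectors, radial), and `n`.
#' @export
make_sensor_array <- function(n = 64, radius = 120, z_min = -60) {
  stopifnot(n >= 1, radius > 0, z_min < radius)
  # Fibonacci lattice on the spherical cap z in (z_min, radius)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  z <- radius - (radius - z_min) * i / n
  r_xy <- sqrt(pmax(radius^2 - z^2, 0))
  th <- golden * seq_len(n)
  pos <- cbind(r_xy * cos(th), r_xy * sin(th), z)
  ori <- pos / sqrt(rowSums(pos^2))
  structure(list(positions = pos, orientations = ori, n = n),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d radial magnetometers, |r| = %.1f mm\n",
              x$n, sqrt(sum(x$positions[1, ]^2))))
  invisible(x)
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form (Sarvas) field of a current dipole inside a spherically
#' symmetric volume conductor, evaluated at points outside the conductor.
#' Positions are in mm and converted to metres internally; the dipole
#' moment is in A*m and the returned field in tesla.
#'
#' @param dipole_position Length-3 dipole location, mm.
#' @param dipole_moment Length-3 dipole moment, A*m.
#' @param sensor_position Length-3 field point, mm, strictly farther from
#'   `sphere_center` than the dipole.
#' @param sphere_center Length-3 conductor centre, mm.
#' @return Length-3 magnetic field vector, tesla.
#' @export
sarvas_field <- function(dipole_position, dipole_moment, sensor_position,
                         sphere_center = c(0, 0, 0)) {
  r0 <- unname(dipole_position - sphere_center) * 1e-3
  r <- unname(sensor_position - sphere_center) * 1e-3
  q <- unname(dipole_moment)
  nr0 <- sqrt(sum(r0^2))
  nr <- sqrt(sum(r^2))
  if (nr0 < 1e-12) {
    stop("dipole at the sphere centre has no defined tangential direction",
         call. = FALSE)
  }
  if (nr <= nr0) {
    stop("sensor must lie strictly outside the dipole radius", call. = FALSE)
  }
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  adr <- sum(a_vec * r)
  f <- a * (nr * a + nr^2 - sum(r0 * r))
  grad_f <- (a^2 / nr + adr / a + 2 * a + 2 * nr) * r -
    (a + 2 * nr + adr / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  MU0_OVER_4PI / f^2 * (f * qxr0 - sum(qxr0 * r) * grad_f)
}

# Sarvas field of one dipole at all sensors at once (rows = sensors);
# same formula as sarvas_field, vectorized over field points
sarvas_rows <- function(dipole_position, dipole_moment, sensor_positions,
                        sphere_center) {
  r0 <- (dipole_position - sphere_center) * 1e-3
  R <- sweep(sensor_positions, 2L, sphere_center, `-`) * 1e-3
  q <- dipole_moment
  nr0 <- sqrt(sum(r0^2))
  nr <- sqrt(rowSums(R^2))
  if (nr0 < 1e-12) {
    stop("dipole at the sphere centre has no defined tangential direction",
         call. = FALSE)
  }
  if (any(nr <= nr0)) {
    stop("sensor must lie strictly outside the dipole radius", call. = FALSE)
  }
  A <- R - matrix(r0, nrow(R), 3L, byrow = TRUE)
  a <- sqrt(rowSums(A^2))
  adr <- rowSums(A * R)
  f <- a * (nr * a + nr^2 - drop(R %*% r0))
  c1 <- a^2 / nr + adr / a + 2 * a + 2 * nr
  c2 <- a + 2 * nr + adr / a
  grad_f <- c1 * R - outer(c2, r0)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  MU0_OVER_4PI / f^2 *
    (f * matrix(qxr0, nrow(R), 3L, byrow = TRUE) -
       drop(R %*% qxr0) * grad_f)
}

# deterministic tangential unit vector at position p (mm, relative to
# sphere_center): azimuthal direction z_hat x r_hat, with an x-axis fallback
# when p is along z.
tangential_orientation <- function(p) {
  r_hat <- p / sqrt(sum(p^2))
  t_vec <- c(-r_hat[2], r_hat[1], 0)      # z_hat x r_hat
  nt <- sqrt(sum(t_vec^2))
  if (nt < 1e-9) {
    t_vec <- c(1, 0, 0) - r_hat[1] * r_hat # project x_hat to tangent plane
    nt <- sqrt(sum(t_vec^2))
  }
  t_vec / nt
}

#' Build a leadfield matrix for a mesh and sensor array
#'
#' One fixed tangential dipole per mesh vertex: the source orientation at
#' vertex `i` is the azimuthal tangential unit vector at that vertex
#' (relative to the conductor centre), so every source is magnetically
#' visible.  Column `i` holds the sensor-orientation projections of the
#' Sarvas field of a unit (1 A*m) dipole at vertex `i`.
#'
#' @param mesh A [meg_mesh] in the same coordinate frame as `sensors`.
#' @param sensors A `sensor_array` from [make_sensor_array()].
#' @param sphere_center Conductor centre, mm.
#' @return A `leadfield`: list with `L` (N x P matrix, T/(A*m)),
#'   `orientations` (P x 3 source orientations) and `sphere_center`.
#' @export
build_leadfield <- function(mesh, sensors, sphere_center = c(0, 0, 0)) {
  p <- nrow(mesh$vertices)
  n <- sensors$n
  ori <- t(apply(sweep(mesh$vertices, 2L, sphere_center, `-`), 1L,
                 tangential_orientation))
  L <- matrix(0, n, p)
  for (i in seq_len(p)) {
    B <- sarvas_rows(mesh$vertices[i, ], ori[i, ], sensors$positions,
                     sphere_center)
    L[, i] <- rowSums(B * sensors$orientations)
  }
  structure(list(L = L, orientations = ori, sphere_center = sphere_center),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources, |L| ~ %.2e T/(A*m)\n",
              nrow(x$L), ncol(x$L), stats::median(abs(x$L))))
  invisible(x)
}

#' Perturb a leadfield to emulate one subject's anatomy
#'
#' Recomputes leadfield columns from vertex positions displaced
#' tangentially (relative to the conductor centre) by at most
#' `position_jitter_mm`, then scales each column by `1 + g` with
#' `g ~ Uniform(-gain_jitter_fraction, gain_jitter_fraction)`.  With both
#' jitters zero the input is returned unchanged.  Deterministic given
#' `seed`.
#'
#' @param leadfield A `leadfield` from [build_leadfield()].
#' @param mesh The [meg_mesh] the leadfield was built on.
#' @param sensors The `sensor_array` used.
#' @param seed Integer seed.
#' @param position_jitter_mm Maximum tangential vertex displacement, mm.
#' @param gain_jitter_fraction Half-width of the per-column gain factor.
#' @return A jittered `leadfield` of the same shape.
#' @export
jitter_subject <- function(leadfield, mesh, sensors, seed,
                           position_jitter_mm = 3,
                           gain_jitter_fraction = 0.1) {
  stopifnot(position_jitter_mm >= 0, gain_jitter_fraction >= 0)
  if (position_jitter_mm == 0 && gain_jitter_fraction == 0) {
    return(leadfield)
  }
  p <- ncol(leadfield$L)
  n <- nrow(leadfield$L)
  ctr <- leadfield$sphere_center
  draws <- with_seed(seed, list(ang = stats::runif(p) * 2 * pi,
                                mag = stats::runif(p) * position_jitter_mm,
                                g = 1 + (2 * stats::runif(p) - 1) *
                                  gain_jitter_fraction))
  L <- leadfield$L
  ori <- leadfield$orientations
  if (position_jitter_mm > 0) {
    # random in-tangent-plane displacement of each vertex, magnitude
    # uniform in [0, position_jitter_mm]
    ang <- draws$ang
    mag <- draws$mag
    for (i in seq_len(p)) {
      pos <- mesh$vertices[i, ] - ctr
      e1 <- tangential_orientation(pos)
      r_hat <- pos / sqrt(sum(pos^2))
      e2 <- c(r_hat[2] * e1[3] - r_hat[3] * e1[2],
              r_hat[3] * e1[1] - r_hat[1] * e1[3],
              r_hat[1] * e1[2] - r_hat[2] * e1[1])
      newpos <- ctr + pos + mag[i] * (cos(ang[i]) * e1 + sin(ang[i]) * e2)
      B <- sarvas_rows(newpos, ori[i, ], sensors$positions, ctr)
      L[, i] <- rowSums(B * sensors$orientations)
    }
  }
  if (gain_jitter_fraction > 0) {
    L <- sweep(L, 2L, draws$g, `*`)
  }
  structure(list(L = L, orientations = ori, sphere_center = ctr),
            class = "leadfield")
}

# evaluate `expr` under a fixed seed, then restore the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv())
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv()) else if (
      exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
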