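#' Slice recording geometry
#'
#' Describes the three-layered volume conductor used for in-vitro MEA
#' recordings: a non-conducting electrode plate at z = 0, a homogeneous
#' tissue slice from z = 0 to z = h, and an infinitely thick saline bath
#' above.
#'
#' @param h Slice thickness in metres (default 200 um).
#' @param sigma_t Tissue conductivity in S/m.  May be complex for a
#'   capacitive (frequency-dependent) medium at a single frequency.
#' @param sigma_s Bath (saline) conductivity in S/m; must be real and
#'   strictly positive.
#' @param n_terms Truncation order of the image series (default 20, which
#'   is accurate to better than 1e-5 relative for slice geometries of this
#'   scale; see [potential_mea()]).
#' @return An object of class `slice_geometry`.
#' @export
slice_geometry <- function(h = 200e-6, sigma_t = 0.4, sigma_s = 1.5,
                           n_terms = 20L) {
  stopifnot(is.numeric(h), length(h) == 1L, is.finite(h), h > 0)
  if (length(sigma_t) != 1L || !is.finite(Re(sigma_t)) || Re(sigma_t) <= 0)
    stop("'sigma_t' must have a single, positive real part")
  stopifnot(is.numeric(sigma_s), length(sigma_s) == 1L, is.finite(sigma_s))
  if (sigma_s <= 0)
    stop("'sigma_s' must be strictly positive (with both boundaries ",
         "insulating the image series diverges and the potential relative ",
         "to a distant ground is undefined)")
  n_terms <- as.integer(n_terms)
  stopifnot(n_terms >= 1L)
  structure(list(h = h, sigma_t = sigma_t, sigma_s = sigma_s,
                 n_terms = n_terms),
            class = "slice_geometry")
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat("Slice geometry: h =", x$h * 1e6, "um, sigma_t =",
      format(x$sigma_t), "S/m, sigma_s =", x$sigma_s,
      "S/m, image terms =", x$n_terms, "\n")
  invisible(x)
}

## coerce a point (length-3 vector) or n x 3 matrix to a matrix
as_points <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    p <- matrix(p, nrow = 1L)
  }
  stopifnot(ncol(p) == 3L, all(is.finite(p)))
  p
}

point_distance <- function(src, obs) {
  obs <- as_points(obs)
  src <- as_points(src)
  stopifnot(nrow(src) == 1L)
  sqrt((obs[, 1] - src[1, 1])^2 + (obs[, 2] - src[1, 2])^2 +
       (obs[, 3] - src[1, 3])^2)
}

#' Potential of a point current source in an infinite homogeneous medium
#'
#' The fundamental point-source solution: a current `I0` at `src` produces
#' a potential `I0 / (4 * pi * sigma * r)` at distance `r`, with the ground
#' (zero potential) infinitely far away.  The medium is assumed isotropic
#' and homogeneous; `sigma` may be complex to describe a capacitive medium
#' at a single frequency, in which case the returned value is the complex
#' phasor amplitude.
#'
#' @param src Source position, length-3 vector `(x, y, z)` in metres.
#' @param I0 Source current in amperes (scalar).
#' @param obs Observation point(s): length-3 vector or n x 3 matrix.
#' @param sigma Conductivity in S/m (positive real part).
#' @return Potential(s) in volts, one per observation point.
#' @export
potential_homogeneous <- function(src, I0, obs, sigma) {
  if (length(sigma) != 1L || Re(sigma) <= 0)
    stop("'sigma' must be a single conductivity with positive real part")
  r <- point_distance(src, obs)
  if (any(r == 0))
    stop("coincident source and observation point")
  I0 / (4 * pi * sigma * r)
}

#' Potential on the MEA plane for a source in saline above a plate
#'
#' For a point source at height `src[3] > 0` in a saline half-space above a
#' non-conducting electrode plate, the potential on the plate (z = 0) is
#' twice the infinite-medium value: `I0 / (2 * pi * sigma_s * r)`.
#'
#' @inheritParams potential_homogeneous
#' @param obs Observation point(s) on the plane z = 0.
#' @param sigma_s Saline conductivity in S/m (real, positive).
#' @return Potential(s) in volts.
#' @export
potential_saline_halfspace <- function(src, I0, obs, sigma_s) {
  src <- as_points(src)
  obs <- as_points(obs)
  if (src[1, 3] <= 0)
    stop("source must lie above the electrode plate (src z > 0)")
  if (any(abs(obs[, 3]) > 1e-12))
    stop("observation points must lie on the electrode plane z = 0")
  if (length(sigma_s) != 1L || !is.numeric(sigma_s) || sigma_s <= 0)
    stop("'sigma_s' must be a single positive real conductivity")
  r <- point_distance(src, obs)
  if (any(r == 0)) stop("coincident source and observation point")
  I0 / (2 * pi * sigma_s * r)
}

#' Method-of-images potential on the MEA plane under a slice
#'
#' Extracellular potential at the electrode-slice boundary (z = 0) of the
#' three-layered medium (non-conducting plate, tissue slice of thickness
#' `h` and conductivity `sigma_t`, infinite bath of conductivity
#' `sigma_s`), for a point source inside the slice.  Computed as a
#' truncated image series:
#'
#' \deqn{\phi(x,y,0) = 2\phi_h(x,y,0) + 2\sum_{n=1}^{N} W^n
#'   \left[\phi_h(x,y,2nh) + \phi_h(x,y,-2nh)\right],\quad
#'   W = \frac{\sigma_T - \sigma_S}{\sigma_T + \sigma_S}}
#'
#' where \eqn{\phi_h} is the homogeneous solution with conductivity
#' `sigma_t`.  For `sigma_t == sigma_s` (W = 0) this reduces exactly to
#' twice the homogeneous potential, as expected for a half-space above an
#' insulating plate.  The series converges geometrically; the default 20
#' terms are accurate to better than 1e-5 relative over MEA-scale
#' geometries.
#'
#' @inheritParams potential_homogeneous
#' @param obs Observation point(s) on the plane z = 0.
#' @param geom A [slice_geometry()].
#' @return Potential(s) in volts (complex if `sigma_t` is complex).
#' @export
potential_mea <- function(src, I0, obs, geom) {
  stopifnot(inherits(geom, "slice_geometry"))
  src <- as_points(src)
  obs <- as_points(obs)
  if (src[1, 3] <= 0 || src[1, 3] >= geom$h)
    stop("source must lie strictly inside the slice (0 < z < h)")
  if (any(abs(obs[, 3]) > 1e-12))
    stop("observation points must lie on the electrode plane z = 0")
  rho2 <- (obs[, 1] - src[1, 1])^2 + (obs[, 2] - src[1, 2])^2
  zp <- src[1, 3]
  r0 <- sqrt(rho2 + zp^2)
  if (any(r0 == 0)) stop("coincident source and observation point")
  w <- (geom$sigma_t - geom$sigma_s) / (geom$sigma_t + geom$sigma_s)
  total <- 2 / r0
  if (w != 0) {
    for (n in seq_len(geom$n_terms)) {
      rn_a <- sqrt(rho2 + (2 * n * geom$h - zp)^2)
      rn_b <- sqrt(rho2 + (2 * n * geom$h + zp)^2)
      total <- total + 2 * w^n * (1 / rn_a + 1 / rn_b)
    }
  }
  I0 * total / (4 * pi * geom$sigma_t)
}

#' Point-source potential in a homogeneous anisotropic medium
#'
#' Infinite-medium potential when the conductivity differs along the three
#' coordinate axes:
#' \deqn{\phi = \frac{I_0}{4\pi\sqrt{\sigma_y\sigma_z\Delta x^2 +
#'   \sigma_x\sigma_z\Delta y^2 + \sigma_x\sigma_y\Delta z^2}}}
#' Reduces to [potential_homogeneous()] when all three conductivities are
#' equal.  Useful for generating anisotropic test data, e.g. to emulate the
#' vertically aligned apical dendrites of cortex.
#'
#' @inheritParams potential_homogeneous
#' @param sigma Length-3 numeric vector `(sigma_x, sigma_y, sigma_z)` in
#'   S/m, all strictly positive.
#' @return Potential(s) in volts.
#' @export
potential_homogeneous_anisotropic <- function(src, I0, obs, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 3L, all(sigma > 0))
  src <- as_points(src)
  obs <- as_points(obs)
  dx2 <- (obs[, 1] - src[1, 1])^2
  dy2 <- (obs[, 2] - src[1, 2])^2
  dz2 <- (obs[, 3] - src[1, 3])^2
  den <- sqrt(sigma[2] * sigma[3] * dx2 + sigma[1] * sigma[3] * dy2 +
              sigma[1] * sigma[2] * dz2)
  if (any(den == 0)) stop("coincident source and observation point")
  I0 / (4 * pi * den)
}
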