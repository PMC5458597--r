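# Planck constant x speed of light, keV * Angstrom (CODATA 2018)
.hc_keV_A <- 12.398419843320026

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Describe a flat 2D area detector
#'
#' A detector is a regular grid of `n_slow` x `n_fast` rectangular pixels.
#' Following common image-array layout, "fast" is the second array axis
#' (columns of the count matrix) and "slow" the first. Pixel coordinates are
#' 0-based and the point (0, 0) is the *centre* of the corner pixel.
#'
#' @param n_slow,n_fast Pixel counts along the slow/fast axes (>= 16).
#' @param pixel_size_slow,pixel_size_fast Pixel pitch in mm (> 0). The fast
#'   pitch defaults to the slow pitch (square pixels).
#' @param static_mask Logical matrix of dim `c(n_slow, n_fast)`; `TRUE`
#'   marks pixels that never contribute (module gaps, dead zones). Defaults
#'   to an all-`FALSE` mask.
#' @param saturation Count value at which the detector saturates; used as the
#'   sentinel value written into masked/gap pixels by the synthetic
#'   generators so that threshold masking exercises the overexposed path.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(n_slow, n_fast,
                          pixel_size_slow, pixel_size_fast = pixel_size_slow,
                          static_mask = NULL, saturation = 2^20) {
  n_slow <- as.integer(n_slow); n_fast <- as.integer(n_fast)
  stopifnot(n_slow >= 16L, n_fast >= 16L,
            pixel_size_slow > 0, pixel_size_fast > 0, saturation > 0)
  if (is.null(static_mask)) {
    static_mask <- matrix(FALSE, n_slow, n_fast)
  }
  if (!is.logical(static_mask) || !identical(dim(static_mask), c(n_slow, n_fast))) {
    stop("`static_mask` must be a logical matrix of dim (n_slow, n_fast)")
  }
  structure(list(n_slow = n_slow, n_fast = n_fast,
                 pixel_size_slow = pixel_size_slow,
                 pixel_size_fast = pixel_size_fast,
                 static_mask = static_mask, saturation = saturation),
            class = "detector_spec")
}

#' @export
format.detector_spec <- function(x, ...) {
  sprintf("<detector_spec> %d x %d px, pitch %g x %g mm, %d masked",
          x$n_slow, x$n_fast, x$pixel_size_slow, x$pixel_size_fast,
          sum(x$static_mask))
}

#' @export
print.detector_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' The six-parameter diffraction geometry
#'
#' Parametrizes the mapping from detector pixels to scattering angles by six
#' independent quantities: the sample-to-detector distance along the direct
#' beam, the beam-centre pixel coordinates (fractional, may lie off the
#' detector), two orthogonal detector tilts, and the wavelength (or,
#' equivalently, the X-ray energy; exactly one is stored, the other derived
#' via E[keV] * lambda[A] = 12.3984...).
#'
#' Detector pose model: the detector plane is first rotated by `tilt_pitch`
#' about the lab horizontal axis (the untilted fast axis), then by
#' `tilt_yaw` about the lab vertical axis, then positioned so the direct
#' beam pierces it at the beam-centre pixel at the stated distance.
#'
#' @param distance Sample-to-detector distance in mm (> 0), measured to the
#'   beam-centre point on the detector along the direct beam.
#' @param beam_centre_fast,beam_centre_slow Beam-centre coordinates in
#'   fractional 0-based pixels.
#' @param tilt_pitch,tilt_yaw Detector tilts in degrees, |tilt| < 90.
#' @param wavelength X-ray wavelength in Angstrom (give this or `energy_keV`).
#' @param energy_keV X-ray energy in keV (alternative to `wavelength`).
#' @param detector A [detector_spec()].
#' @return An object of class `diffraction_geometry`.
#' @export
diffraction_geometry <- function(distance, beam_centre_fast, beam_centre_slow,
                                 tilt_pitch = 0, tilt_yaw = 0,
                                 wavelength = NULL, energy_keV = NULL,
                                 detector) {
  if (is.null(wavelength) == is.null(energy_keV)) {
    stop("give exactly one of `wavelength` and `energy_keV`")
  }
  if (is.null(wavelength)) wavelength <- .hc_keV_A / energy_keV
  stopifnot(inherits(detector, "detector_spec"),
            distance > 0, wavelength > 0,
            abs(tilt_pitch) < 90, abs(tilt_yaw) < 90)
  structure(list(distance = distance,
                 beam_centre_fast = beam_centre_fast,
                 beam_centre_slow = beam_centre_slow,
                 tilt_pitch = tilt_pitch, tilt_yaw = tilt_yaw,
                 wavelength = wavelength, detector = detector),
            class = "diffraction_geometry")
}

#' @export
format.diffraction_geometry <- function(x, ...) {
  sprintf(paste0("<diffraction_geometry> D = %.4g mm, centre (%.3f, %.3f) px,",
                 " pitch %.4g deg, yaw %.4g deg, lambda %.6g A (%.5g keV)"),
          x$distance, x$beam_centre_fast, x$beam_centre_slow,
          x$tilt_pitch, x$tilt_yaw, x$wavelength, geom_energy(x))
}

#' @export
print.diffraction_geometry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @rdname diffraction_geometry
#' @param geom A `diffraction_geometry`.
#' @export
geom_energy <- function(geom) .hc_keV_A / geom$wavelength

#' @rdname diffraction_geometry
#' @export
set_energy <- function(geom, energy_keV) {
  stopifnot(energy_keV > 0)
  geom$wavelength <- .hc_keV_A / energy_keV
  geom
}

#' @rdname diffraction_geometry
#' @export
set_wavelength <- function(geom, wavelength) {
  stopifnot(wavelength > 0)
  geom$wavelength <- wavelength
  geom
}

# Orthonormal detector basis in the lab frame: columns e_fast, e_slow, normal.
# Lab: x horizontal (+fast when untilted), y vertical (+slow), z along beam.
detector_basis <- function(geom) {
  p <- deg2rad(geom$tilt_pitch); y <- deg2rad(geom$tilt_yaw)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(p), sin(p),
                 0, -sin(p), cos(p)), 3, 3)
  Ry <- matrix(c(cos(y), 0, -sin(y),
                 0, 1, 0,
                 sin(y), 0, cos(y)), 3, 3)
  Ry %*% Rx
}

# Lab-frame position (mm) of fractional pixel coordinates; returns list of
# x, y, z vectors the same shape as the inputs.
pixel_to_xyz <- function(geom, fast, slow) {
  B <- detector_basis(geom)
  u <- (fast - geom$beam_centre_fast) * geom$detector$pixel_size_fast
  v <- (slow - geom$beam_centre_slow) * geom$detector$pixel_size_slow
  list(x = u * B[1, 1] + v * B[1, 2],
       y = u * B[2, 1] + v * B[2, 2],
       z = u * B[3, 1] + v * B[3, 2] + geom$distance)
}

#' Map pixel coordinates to scattering angles
#'
#' Computes, for the ray from the sample through each (fractional) pixel
#' position, the scattering angle 2-theta, the azimuth chi, the momentum
#' transfer q = 4 pi sin(theta) / lambda and the resolution d = 2 pi / q.
#' Chi is 0 along the +fast axis, increases counter-clockwise viewed from
#' the sample, and lies in (-180, 180].
#'
#' @param geom A [diffraction_geometry()].
#' @param fast,slow Equal-length vectors of fractional 0-based pixel
#'   coordinates (may be off-detector).
#' @return A tibble with columns `fast`, `slow`, `two_theta` (deg), `chi`
#'   (deg), `q` (1/Angstrom) and `d` (Angstrom; `Inf` at the direct beam).
#' @export
pixel_to_angles <- function(geom, fast, slow) {
  P <- pixel_to_xyz(geom, fast, slow)
  r <- sqrt(P$x^2 + P$y^2 + P$z^2)
  tt <- acos(pmin(1, pmax(-1, P$z / r)))
  chi <- atan2(P$y, P$x)
  q <- 4 * pi * sin(tt / 2) / geom$wavelength
  tibble::tibble(fast = as.vector(fast), slow = as.vector(slow),
                 two_theta = rad2deg(as.vector(tt)),
                 chi = rad2deg(as.vector(chi)),
                 q = as.vector(q),
                 d = ifelse(as.vector(q) > 0, 2 * pi / as.vector(q), Inf))
}

# Shared grid machinery for per-pixel coordinate maps. `offset` 0 gives
# pixel centres, -0.5 with n+1 points gives the corner grid.
pixel_grid <- function(geom, corners = FALSE) {
  det <- geom$detector
  if (corners) {
    fast <- seq(-0.5, det$n_fast - 0.5, by = 1)
    slow <- seq(-0.5, det$n_slow - 0.5, by = 1)
  } else {
    fast <- seq_len(det$n_fast) - 1
    slow <- seq_len(det$n_slow) - 1
  }
  list(fast = matrix(fast, length(slow), length(fast), byrow = TRUE),
       slow = matrix(slow, length(slow), length(fast)))
}

coord_map <- function(geom, what = c("q", "chi", "two_theta", "d"),
                      corners = FALSE) {
  what <- match.arg(what)
  g <- pixel_grid(geom, corners)
  P <- pixel_to_xyz(geom, g$fast, g$slow)
  r <- sqrt(P$x^2 + P$y^2 + P$z^2)
  out <- switch(what,
    two_theta = rad2deg(acos(pmin(1, pmax(-1, P$z / r)))),
    chi = rad2deg(atan2(P$y, P$x)),
    q = 4 * pi * sin(acos(pmin(1, pmax(-1, P$z / r))) / 2) / geom$wavelength,
    d = {
      q <- 4 * pi * sin(acos(pmin(1, pmax(-1, P$z / r))) / 2) / geom$wavelength
      ifelse(q > 0, 2 * pi / q, Inf)
    })
  matrix(out, nrow(g$fast), ncol(g$fast))
}

#' Per-pixel coordinate maps
#'
#' `q_map()` and `chi_map()` return matrices (dim `n_slow` x `n_fast`) of the
#' radial coordinate q (1/Angstrom) and the azimuth chi (deg) of every pixel
#' centre, consistent with [pixel_to_angles()] at every pixel.
#'
#' @inheritParams pixel_to_angles
#' @return A numeric matrix of dim `c(n_slow, n_fast)`.
#' @export
q_map <- function(geom) coord_map(geom, "q")

#' @rdname q_map
#' @export
chi_map <- function(geom) coord_map(geom, "chi")

#' @rdname q_map
#' @export
two_theta_map <- function(geom) coord_map(geom, "two_theta")

#' An ellipse on the detector, in pixel coordinates
#'
#' @param centre_fast,centre_slow Centre, fractional pixels.
#' @param semi_major,semi_minor Semi-axes in pixels, `semi_major >= semi_minor > 0`.
#' @param orientation Angle of the major axis from the +fast axis, degrees,
#'   in (-90, 90].
#' @return An object of class `conic`.
#' @export
conic <- function(centre_fast, centre_slow, semi_major, semi_minor, orientation) {
  stopifnot(semi_major >= semi_minor, semi_minor > 0)
  orientation <- ((orientation + 90) %% 180) - 90
  if (orientation <= -90) orientation <- orientation + 180
  structure(list(centre_fast = centre_fast, centre_slow = centre_slow,
                 semi_major = semi_major, semi_minor = semi_minor,
                 orientation = orientation),
            class = "conic")
}

#' @export
format.conic <- function(x, ...) {
  sprintf("<conic> centre (%.3f, %.3f) px, a = %.3f, b = %.3f px, %.3f deg",
          x$centre_fast, x$centre_slow, x$semi_major, x$semi_minor,
          x$orientation)
}

#' @export
print.conic <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Points on a conic
#'
#' Parametric sampling of an ellipse: `centre + a cos t (major dir) +
#' b sin t (minor dir)`.
#'
#' @param con A [conic()].
#' @param t Parameter values in radians (default 360 equally spaced).
#' @return Tibble with columns `fast`, `slow`.
#' @export
conic_points <- function(con, t = seq(0, 2 * pi, length.out = 361)[-361]) {
  th <- deg2rad(con$orientation)
  ca <- cos(th); sa <- sin(th)
  xa <- con$semi_major * cos(t); yb <- con$semi_minor * sin(t)
  tibble::tibble(fast = con$centre_fast + xa * ca - yb * sa,
                 slow = con$centre_slow + xa * sa + yb * ca)
}

# General conic a x^2 + b xy + c y^2 + d x + e y + f = 0 -> ellipse params.
# Coordinates relative to whatever origin the coefficients use.
conic_from_coeffs <- function(co) {
  a <- co[1]; b <- co[2]; cc <- co[3]; d <- co[4]; e <- co[5]; f <- co[6]
  disc <- b^2 - 4 * a * cc
  if (!is.finite(disc) || disc >= 0) {
    stop("conic is not an ellipse (discriminant >= 0)")
  }
  x0 <- (2 * cc * d - b * e) / disc
  y0 <- (2 * a * e - b * d) / disc
  f0 <- f + (d * x0 + e * y0) / 2
  M <- matrix(c(a, b / 2, b / 2, cc), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  ax2 <- -f0 / ev$values          # squared semi-axes
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) stop("degenerate ellipse")
  imaj <- which.max(ax2)
  semi_major <- sqrt(ax2[imaj]); semi_minor <- sqrt(min(ax2))
  vmaj <- ev$vectors[, imaj]
  conic(x0, y0, semi_major, semi_minor, rad2deg(atan2(vmaj[2], vmaj[1])))
}

#' Predict the Debye-Scherrer ring for a d-spacing
#'
#' Intersects the scattering cone `two_theta = 2 asin(lambda / 2d)` with the
#' (possibly tilted) detector plane and returns the resulting ellipse in
#' pixel coordinates, in closed form. For zero tilt this is a circle of
#' radius `distance * tan(two_theta)` centred at the beam centre.
#'
#' @inheritParams pixel_to_angles
#' @param d_spacing Lattice spacing in Angstrom; requires
#'   `wavelength < 2 * d_spacing` (Bragg condition).
#' @return A [conic()].
#' @export
predict_ring <- function(geom, d_spacing) {
  if (geom$wavelength >= 2 * d_spacing) {
    stop(sprintf("reflection unreachable: lambda = %g >= 2 d = %g",
                 geom$wavelength, 2 * d_spacing))
  }
  tt <- 2 * asin(geom$wavelength / (2 * d_spacing))
  B <- detector_basis(geom)
  a3 <- B[3, 1]; b3 <- B[3, 2]
  c2 <- cos(tt)^2; s2 <- 1 - c2
  D <- geom$distance
  pf <- geom$detector$pixel_size_fast; ps <- geom$detector$pixel_size_slow
  # conic in (u, v) mm offsets from beam-centre point:
  # (a3^2-c2) u^2 + 2 a3 b3 uv + (b3^2-c2) v^2
  #   + 2 D a3 s2 u + 2 D b3 s2 v + D^2 s2 = 0
  co <- c((a3^2 - c2) * pf^2,
          2 * a3 * b3 * pf * ps,
          (b3^2 - c2) * ps^2,
          2 * D * a3 * s2 * pf,
          2 * D * b3 * s2 * ps,
          D^2 * s2)
  con <- conic_from_coeffs(co)
  con$centre_fast <- con$centre_fast + geom$beam_centre_fast
  con$centre_slow <- con$centre_slow + geom$beam_centre_slow
  con
}
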