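# Seeded, bit-reproducible generators for every fixture the test surface
# needs: calibrant ring images, multi-distance series, peak-shift series
# and oriented-scatter grid scans. Ring profiles are Gaussian in q (not in
# radius) so that q-space oracles are exact.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

eval_background <- function(background, q) {
  if (length(background) == 1) return(rep(background, length(q)))
  # polynomial coefficients in q, lowest order first
  out <- 0
  for (k in seq_along(background)) out <- out + background[k] * q^(k - 1)
  out
}

#' Render a synthetic calibrant ring image
#'
#' Per-pixel intensity is `background(q) + sum_k A_k exp(-(q - q_k)^2 /
#' (2 sigma_q^2))` over the calibrant rings reachable on the detector,
#' optionally divided by the solid-angle and polarization factors (so that
#' applying [correct_solid_angle()] / [correct_polarization()] recovers the
#' ideal pattern), with Poisson noise applied last under the stated seed.
#' Static-mask pixels are set to the detector saturation sentinel and
#' masked.
#'
#' @param geometry A [diffraction_geometry()].
#' @param cal A [load_calibrant()] standard.
#' @param ring_amplitudes Peak amplitude in counts, recycled over rings.
#' @param ring_width_q Gaussian sigma of each ring in q (1/Angstrom).
#' @param background Constant counts, or polynomial coefficients in q
#'   (lowest order first).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed for the Poisson draw.
#' @param apply_inverse_corrections Divide by solid-angle (and, if
#'   `polarization_fraction` is not `NULL`, polarization) factors.
#' @param polarization_fraction Optional xi used when inverting corrections.
#' @return A [frame()]; metadata records the ring q positions as `q_rings`.
#' @export
render_calibration_image <- function(geometry, cal, ring_amplitudes = 1000,
                                     ring_width_q = 0.02, background = 50,
                                     noise = c("none", "poisson"),
                                     seed = NULL,
                                     apply_inverse_corrections = FALSE,
                                     polarization_fraction = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(ring_amplitudes >= 0), ring_width_q > 0)
  det <- geometry$detector
  qm <- q_map(geometry)
  ttmax <- max(coord_map(geometry, "two_theta"))
  rings <- ring_positions(cal, geometry$wavelength, ttmax)
  img <- matrix(eval_background(background, as.vector(qm)),
                det$n_slow, det$n_fast)
  if (nrow(rings) == 0) {
    warning("no calibrant ring reachable on the detector; background-only image")
  } else {
    amps <- rep_len(ring_amplitudes, nrow(rings))
    for (k in seq_len(nrow(rings))) {
      dq <- qm - rings$q[k]
      hit <- abs(dq) < 6 * ring_width_q
      img[hit] <- img[hit] + amps[k] * exp(-dq[hit]^2 / (2 * ring_width_q^2))
    }
  }
  if (apply_inverse_corrections) {
    img <- img / solid_angle_factor(geometry)
    if (!is.null(polarization_fraction)) {
      img <- img * polarization_factor(geometry, polarization_fraction)
    }
  }
  if (noise == "poisson") {
    img[] <- with_seed(seed, stats::rpois(length(img), lambda = pmax(img, 0)))
  }
  mask <- det$static_mask
  img[mask] <- det$saturation
  frame(img, mask = mask,
        metadata = list(q_rings = rings$q, d_rings = rings$d,
                        ring_width_q = ring_width_q))
}

#' Render a multi-distance calibration series
#'
#' One image per distance increment; the geometry is identical across the
#' series except `distance = D0 + delta_i` (shared beam centre, zero
#' drift). Noise seeds are derived per frame from `seed` so frames are
#' independent but the series is reproducible.
#'
#' @inheritParams render_calibration_image
#' @param distance_increments Numeric vector of increments in mm; all
#'   resulting distances must stay positive.
#' @param ... Passed on to [render_calibration_image()].
#' @return List of [frame()]s, one per increment.
#' @export
render_distance_series <- function(geometry, cal, distance_increments,
                                   seed = NULL, ...) {
  if (any(geometry$distance + distance_increments <= 0)) {
    stop("increment drives sample-detector distance <= 0")
  }
  lapply(seq_along(distance_increments), function(i) {
    g <- geometry
    g$distance <- geometry$distance + distance_increments[i]
    render_calibration_image(g, cal,
                             seed = if (is.null(seed)) NULL else seed + i,
                             ...)
  })
}

#' Render a peak-shift profile series
#'
#' A stack of 1D profiles, each a Gaussian peak on a linear background,
#' with the peak centre and FWHM following the supplied per-frame
#' trajectories (e.g. a step change at a known frame, emulating a
#' solid-state transformation). Ground truth is attached as metadata.
#'
#' @param n_frames Number of frames.
#' @param centre_trajectory,fwhm_trajectory Length-`n_frames` vectors, in
#'   axis units.
#' @param axis Radial axis values (default 300 points over 1..10).
#' @param amplitude Peak amplitude in counts.
#' @param background Intercept/slope of the linear baseline, length 2.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed.
#' @return A [scan_dataset()] of rank 2 (`n_frames` x axis) with
#'   `signal_rank = 1`; `metadata$truth` is a tibble of the trajectories.
#' @export
render_peak_shift_series <- function(n_frames, centre_trajectory,
                                     fwhm_trajectory,
                                     axis = seq(1, 10, length.out = 300),
                                     amplitude = 1000,
                                     background = c(100, 5),
                                     noise = c("none", "poisson"),
                                     seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(centre_trajectory) == n_frames,
            length(fwhm_trajectory) == n_frames)
  sigma <- fwhm_trajectory / (2 * sqrt(2 * log(2)))
  dat <- matrix(0, n_frames, length(axis))
  for (i in seq_len(n_frames)) {
    dat[i, ] <- background[1] + background[2] * axis +
      amplitude * exp(-(axis - centre_trajectory[i])^2 / (2 * sigma[i]^2))
  }
  if (noise == "poisson") {
    dat[] <- with_seed(seed, stats::rpois(length(dat), pmax(dat, 0)))
  }
  scan_dataset(dat,
               axes = list(list(name = "frame", values = seq_len(n_frames)),
                           list(name = "q", values = axis, units = "1/angstrom")),
               signal_rank = 1L,
               metadata = list(truth = tibble::tibble(
                 frame = seq_len(n_frames),
                 centre = centre_trajectory,
                 fwhm = fwhm_trajectory)))
}

#' Render an oriented-scatter 2D grid scan
#'
#' Emulates a SAXS grid scan over a heterogeneous oriented sample (e.g.
#' mineralized tissue): per grid cell the detector image carries, inside a
#' q band, the azimuthal intensity law `I(chi) = iso + aniso *
#' cos^2(chi - direction)`. Sample-stage axes are attached and ground-truth
#' direction/degree maps returned in the metadata.
#'
#' @param grid_shape `c(rows, cols)` of the stage scan.
#' @param geometry Detector geometry for each cell image.
#' @param iso_amplitude,aniso_amplitude Counts; scalars or `rows x cols`
#'   matrices.
#' @param direction_field Orientation in degrees; scalar or matrix.
#' @param q_band `c(q_lo, q_hi)` in 1/Angstrom, `q_lo < q_hi`.
#' @param base_level Flat counts added everywhere (keeps Poisson draws
#'   meaningful outside the band).
#' @param noise,seed As in [render_calibration_image()].
#' @param step_mm Stage step per cell, mm.
#' @return A rank-4 [scan_dataset()] (rows x cols x n_slow x n_fast) with
#'   stage axes; `metadata$truth` holds direction and degree matrices.
#' @export
render_oriented_grid_scan <- function(grid_shape, geometry,
                                      iso_amplitude = 100,
                                      aniso_amplitude = 200,
                                      direction_field = 0,
                                      q_band = c(0.5, 1.5),
                                      base_level = 5,
                                      noise = c("none", "poisson"),
                                      seed = NULL, step_mm = 0.1) {
  noise <- match.arg(noise)
  stopifnot(length(grid_shape) == 2, q_band[1] < q_band[2],
            all(iso_amplitude >= 0), all(aniso_amplitude >= 0))
  rows <- grid_shape[1]; cols <- grid_shape[2]
  as_field <- function(x) if (is.matrix(x)) x else matrix(x, rows, cols)
  iso <- as_field(iso_amplitude); aniso <- as_field(aniso_amplitude)
  dirs <- as_field(direction_field)
  det <- geometry$detector
  qm <- q_map(geometry); chm <- deg2rad(chi_map(geometry))
  band <- qm >= q_band[1] & qm <= q_band[2]
  dat <- array(0, c(rows, cols, det$n_slow, det$n_fast))
  imgs <- with_seed(seed, {
    for (r in seq_len(rows)) for (cc in seq_len(cols)) {
      img <- matrix(base_level, det$n_slow, det$n_fast)
      img[band] <- img[band] + iso[r, cc] +
        aniso[r, cc] * cos(chm[band] - deg2rad(dirs[r, cc]))^2
      if (noise == "poisson") img[] <- stats::rpois(length(img), pmax(img, 0))
      img[det$static_mask] <- det$saturation
      dat[r, cc, , ] <- img
    }
    dat
  })
  # in-band azimuthal law is (base + iso) + aniso cos^2
  degree_truth <- (aniso / 2) / (base_level + iso + aniso / 2)
  scan_dataset(imgs,
               axes = list(
                 list(name = "stage_y", values = (seq_len(rows) - 1) * step_mm,
                      units = "mm"),
                 list(name = "stage_x", values = (seq_len(cols) - 1) * step_mm,
                      units = "mm"),
                 NULL, NULL),
               signal_rank = 2L,
               metadata = list(truth = list(direction = dirs,
                                            degree = degree_truth),
                               q_band = q_band,
                               static_mask = det$static_mask))
}
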