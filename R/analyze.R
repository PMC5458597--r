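# Downstream scalar extraction: single-peak fitting across series
# (position + FWHM trajectories) and azimuthal orientation metrics for
# grid scans.

peak_result <- function(centre = NA_real_, fwhm = NA_real_, area = NA_real_,
                        baseline = c(NA_real_, NA_real_),
                        uncertainties = c(centre = NA_real_, fwhm = NA_real_,
                                          area = NA_real_),
                        success = FALSE, message = NA_character_) {
  structure(list(centre = centre, fwhm = fwhm, area = area,
                 baseline = baseline, uncertainties = uncertainties,
                 success = success, message = message),
            class = "peak_result")
}

#' @export
format.peak_result <- function(x, ...) {
  if (!x$success) return(sprintf("<peak_result> failed: %s", x$message))
  sprintf("<peak_result> centre %.6g +/- %.2g, FWHM %.6g +/- %.2g, area %.6g",
          x$centre, x$uncertainties[["centre"]], x$fwhm,
          x$uncertainties[["fwhm"]], x$area)
}

#' @export
print.peak_result <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @method tidy peak_result
#' @export
tidy.peak_result <- function(x, ...) {
  tibble::tibble(term = c("centre", "fwhm", "area"),
                 estimate = c(x$centre, x$fwhm, x$area),
                 std_error = unname(x$uncertainties[c("centre", "fwhm", "area")]),
                 success = x$success)
}

.fwhm_gauss <- 2 * sqrt(2 * log(2))

#' Fit a single peak with linear baseline
#'
#' Weighted least-squares fit of a Gaussian or pseudo-Voigt peak plus a
#' linear baseline to a window of a radial profile. For the Gaussian shape
#' `FWHM = 2 sqrt(2 ln 2) sigma` exactly; uncertainties come from the fit
#' covariance weighted by the profile errors. A flat window is flagged as
#' a failure rather than fabricating a peak.
#'
#' @param profile A `radial_profile` (or tibble with `radial`, `intensity`
#'   and optional `error`).
#' @param window `c(lo, hi)` in radial-axis units; needs >= 7 valid points.
#' @param shape `"gaussian"` or `"pseudo_voigt"` (shared-width Gaussian /
#'   Lorentzian mix with refined mixing fraction).
#' @param start Optional warm-start `peak_result` (used by [track_peak()]).
#' @return A `peak_result` with `centre`, `fwhm`, `area`, `baseline`
#'   (offset, slope), per-field `uncertainties` and a `success` flag.
#' @export
fit_peak <- function(profile, window, shape = c("gaussian", "pseudo_voigt"),
                     start = NULL) {
  shape <- match.arg(shape)
  x_all <- profile$radial; y_all <- profile$intensity
  e_all <- if ("error" %in% names(profile)) profile$error else NULL
  if (window[1] >= max(x_all, na.rm = TRUE) ||
      window[2] <= min(x_all, na.rm = TRUE)) {
    stop("fit window lies outside the profile axis")
  }
  inw <- x_all >= window[1] & x_all <= window[2] & is.finite(y_all)
  if ("valid" %in% names(profile)) inw <- inw & profile$valid
  if (sum(inw) < 7) {
    return(peak_result(success = FALSE,
                       message = sprintf("only %d valid points in window", sum(inw))))
  }
  x <- x_all[inw]; y <- y_all[inw]
  e <- if (is.null(e_all)) rep(1, length(x)) else e_all[inw]
  e[!is.finite(e) | e <= 0] <- stats::median(e[is.finite(e) & e > 0]) %||% 1
  if (all(!is.finite(e)) || all(is.na(e))) e <- rep(1, length(x))
  sw <- 1 / e
  n <- length(x)
  if (!is.null(start) && isTRUE(start$success)) {
    c0 <- start$centre; f0 <- start$fwhm
    b0 <- start$baseline[1]; s0 <- start$baseline[2]
    a0 <- max(max(y) - (b0 + s0 * (c0 - x[1])), 1e-9)
  } else {
    b0 <- (y[1] + y[n]) / 2
    s0 <- (y[n] - y[1]) / (x[n] - x[1])
    a0 <- max(y - (b0 + s0 * (x - x[1])))
    c0 <- x[which.max(y - (b0 + s0 * (x - x[1])))]
    f0 <- diff(window) / 5
    if (!is.finite(a0) || a0 <= 0) a0 <- max(abs(y - b0), 1e-9)
  }
  x0 <- x[1]
  gauss <- function(p, xx) {
    sig <- abs(p[3]) / .fwhm_gauss
    p[1] * exp(-(xx - p[2])^2 / (2 * sig^2)) + p[4] + p[5] * (xx - x0)
  }
  pvoigt <- function(p, xx) {
    eta <- min(max(p[6], 0), 1)          # clamp keeps eta in [0, 1]
    sig <- abs(p[3]) / .fwhm_gauss
    gam <- abs(p[3]) / 2
    g <- exp(-(xx - p[2])^2 / (2 * sig^2))
    l <- gam^2 / ((xx - p[2])^2 + gam^2)
    p[1] * ((1 - eta) * g + eta * l) + p[4] + p[5] * (xx - x0)
  }
  model <- if (shape == "gaussian") gauss else pvoigt
  p0 <- c(a0, c0, f0, b0, s0)
  if (shape == "pseudo_voigt") p0 <- c(p0, 0.3)
  fn <- function(p) sw * (model(p, x) - y)
  sc <- c(max(abs(a0), 1e-6), diff(window), diff(window) / 4,
          max(abs(b0), 1), max(abs(s0), 1e-3))
  if (shape == "pseudo_voigt") sc <- c(sc, 1)
  fit <- tryCatch(lm_least_squares(p0, fn, scale = sc, rel_tol = 1e-12,
                                   max_iter = 200L, cond_max = 1e14),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(peak_result(success = FALSE, message = "fit did not converge"))
  }
  p <- fit$par
  amp <- p[1]; fwhm <- abs(p[3])
  rms <- sqrt(mean((fit$residuals / sw)^2))
  thr <- max(3 * rms,
             if (all(e == 1)) 0 else 2 * stats::median(e),
             1e-6 * max(abs(y), 1))
  ok <- is.finite(amp) && amp > thr && fwhm > 0 &&
        p[2] > window[1] && p[2] < window[2]
  unc <- c(centre = NA_real_, fwhm = NA_real_, area = NA_real_)
  area <- if (shape == "gaussian") {
    amp * (fwhm / .fwhm_gauss) * sqrt(2 * pi)
  } else {
    eta <- min(max(p[6], 0), 1)
    amp * ((1 - eta) * (fwhm / .fwhm_gauss) * sqrt(2 * pi) +
           eta * pi * fwhm / 2)
  }
  if (!is.null(fit$cov)) {
    unc["centre"] <- sqrt(max(fit$cov[2, 2], 0))
    unc["fwhm"] <- sqrt(max(fit$cov[3, 3], 0))
    # area propagated from amplitude and width (gaussian form)
    da <- area / amp; dw <- area / fwhm
    unc["area"] <- sqrt(max(da^2 * fit$cov[1, 1] + dw^2 * fit$cov[3, 3] +
                            2 * da * dw * fit$cov[1, 3], 0))
  }
  if (!ok) {
    return(peak_result(centre = p[2], fwhm = fwhm, area = area,
                       baseline = c(p[4], p[5]), uncertainties = unc,
                       success = FALSE, message = "no significant peak"))
  }
  peak_result(centre = p[2], fwhm = fwhm, area = area,
              baseline = c(p[4], p[5]), uncertainties = unc, success = TRUE)
}

#' Track a peak across a series of profiles
#'
#' Fits the same window independently in every frame, warm-starting each
#' fit from the previous frame's solution (stabilizes gradual drifts).
#' Per-frame failures are recorded without aborting the series, so the
#' output always has one row per frame (scan rank preserved: one scalar
#' set per frame).
#'
#' @param series A [scan_dataset()] with `signal_rank = 1`, a matrix
#'   (frames x points), or a list of `radial_profile`s on a common axis.
#' @param window,shape As in [fit_peak()].
#' @param axis Radial axis values (required for a bare matrix).
#' @return A tibble: `frame`, `centre`, `fwhm`, `area`,
#'   `centre_err`, `fwhm_err`, `success`.
#' @export
track_peak <- function(series, window, shape = "gaussian", axis = NULL) {
  if (inherits(series, "scan_dataset")) {
    stopifnot(series$signal_rank == 1L)
    mat <- series$data
    if (length(dim(mat)) != 2) stop("track_peak expects a rank-2 profile stack")
    ax <- series$axes[[2]]
    axis <- if (!is.null(ax)) ax$values else seq_len(ncol(mat))
    profiles <- lapply(seq_len(nrow(mat)), function(i)
      tibble::tibble(radial = axis, intensity = mat[i, ]))
  } else if (is.matrix(series)) {
    if (is.null(axis)) axis <- seq_len(ncol(series))
    profiles <- lapply(seq_len(nrow(series)), function(i)
      tibble::tibble(radial = axis, intensity = series[i, ]))
  } else {
    profiles <- series
  }
  prev <- NULL
  rows <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    pr <- tryCatch(fit_peak(profiles[[i]], window, shape, start = prev),
                   error = function(e) peak_result(success = FALSE,
                                                   message = conditionMessage(e)))
    if (pr$success) prev <- pr
    rows[[i]] <- tibble::tibble(
      frame = i, centre = pr$centre, fwhm = pr$fwhm, area = pr$area,
      centre_err = pr$uncertainties[["centre"]],
      fwhm_err = pr$uncertainties[["fwhm"]],
      success = pr$success)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("peak_track", class(out))
  out
}

#' Azimuthal profile over a q band
#'
#' Weighted mean of the cake cells whose radial bin centres fall in the
#' band, per azimuth row.
#'
#' @param cake A [cake_remap()] grid.
#' @param q_band `c(lo, hi)` in the cake's radial unit.
#' @return Tibble `chi`, `intensity`, `error`, `weight`, `valid`, ordered
#'   by chi; class `azimuthal_profile`.
#' @export
azimuthal_profile <- function(cake, q_band) {
  stopifnot(inherits(cake, "cake_grid"))
  inb <- cake$radial_centres >= q_band[1] & cake$radial_centres <= q_band[2]
  if (!any(inb)) stop("q band does not overlap the cake's radial axis")
  w <- cake$weights[, inb, drop = FALSE]
  iv <- ifelse(cake$valid[, inb, drop = FALSE],
               cake$intensity[, inb, drop = FALSE], 0)
  ev <- ifelse(cake$valid[, inb, drop = FALSE],
               cake$errors[, inb, drop = FALSE], 0)
  wsum <- rowSums(w)
  valid <- wsum > 0
  out <- tibble::tibble(
    chi = cake$azimuth_centres,
    intensity = ifelse(valid, rowSums(iv * w) / wsum, NA_real_),
    error = ifelse(valid, sqrt(rowSums((ev * w)^2)) / wsum, NA_real_),
    weight = wsum, valid = valid)
  out <- out[order(out$chi), ]
  class(out) <- c("azimuthal_profile", class(out))
  out
}

#' Degree and direction of preferred orientation
#'
#' From an azimuthal intensity profile: the isotropic level `I_iso` is a
#' low percentile of the valid bins (default the 5th, for noise
#' robustness); the degree of orientation is the proportion of scatter
#' above that floor, `sum(I - I_iso)_+ / sum(I)`, and the direction is the
#' pi-periodic circular mean `0.5 * Arg sum (I - I_iso)_+ exp(2 i chi)`
#' mapped to `(-90, 90]`. An isotropic profile yields degree 0 with the
#' direction flagged invalid.
#'
#' @param azprof An [azimuthal_profile()] (or tibble with `chi`,
#'   `intensity`), >= 8 valid bins.
#' @param floor_percentile Percentile (0-100) defining `I_iso`; 0 uses the
#'   minimum.
#' @return A tibble row: `degree` in `[0, 1]`, `direction` in `(-90, 90]`
#'   degrees (`NA` when undefined), `direction_valid`, `total_intensity`.
#' @export
orientation_metrics <- function(azprof, floor_percentile = 5) {
  ok <- is.finite(azprof$intensity)
  if ("valid" %in% names(azprof)) ok <- ok & azprof$valid
  if (sum(ok) < 8) stop("orientation_metrics: fewer than 8 valid azimuth bins")
  I <- azprof$intensity[ok]; chi <- deg2rad(azprof$chi[ok])
  total <- sum(I)
  if (total <= 0) stop("orientation_metrics: non-positive total intensity")
  iso <- stats::quantile(I, probs = floor_percentile / 100, names = FALSE)
  excess <- pmax(I - iso, 0)
  degree <- min(max(sum(excess) / total, 0), 1)
  z <- sum(excess * exp(2i * chi))
  dir_valid <- Mod(z) > 1e-9 * total && degree > 0
  direction <- if (dir_valid) {
    dd <- rad2deg(Arg(z) / 2)
    if (dd <= -90) dd <- dd + 180
    if (dd > 90) dd <- dd - 180
    dd
  } else NA_real_
  tibble::tibble(degree = degree, direction = direction,
                 direction_valid = dir_valid, total_intensity = total)
}

#' Map orientation over a grid scan
#'
#' Applies [orientation_metrics()] per scan cell: each detector frame is
#' azimuthally binned inside the q band (through the geometry's chi map)
#' and summarized to a degree and direction. Output rank equals the scan
#' rank; stage axes propagate verbatim.
#'
#' @param scan A rank >= 3 [scan_dataset()] with 2D detector frames.
#' @param geom The [diffraction_geometry()] shared by all frames.
#' @param q_band `c(lo, hi)` in 1/Angstrom.
#' @param n_azimuthal Azimuth bins per cell.
#' @param floor_percentile Passed to [orientation_metrics()].
#' @param mask Optional static mask applied to every frame.
#' @return An `orientation_map`: `degree` and `direction` arrays of the
#'   scan shape, `total` array, logical `valid`, and the stage `axes`.
#' @export
orientation_map <- function(scan, geom, q_band, n_azimuthal = 72,
                            floor_percentile = 5, mask = NULL) {
  stopifnot(inherits(scan, "scan_dataset"), scan$signal_rank == 2L)
  sr <- scan_rank(scan)
  if (sr < 1) stop("orientation_map needs at least one scan dimension")
  d <- dim(scan$data)
  scan_dims <- d[seq_len(sr)]
  n <- prod(scan_dims)
  if (is.null(mask)) mask <- geom$detector$static_mask
  qm <- q_map(geom); chm <- chi_map(geom)
  band <- qm >= q_band[1] & qm <= q_band[2] & !mask
  if (!any(band)) stop("q band selects no pixels")
  aedges <- seq(-180, 180, length.out = n_azimuthal + 1)
  abin <- findInterval(chm[band], aedges, rightmost.closed = TRUE)
  degree <- direction <- total <- array(NA_real_, scan_dims)
  valid <- array(FALSE, scan_dims)
  for (i in seq_len(n)) {
    img <- scan_slice(scan, i)
    s <- rowsum(cbind(1, img[band]), abin)
    prof <- tibble::tibble(
      chi = (aedges[-1] + aedges[-(n_azimuthal + 1)]) / 2,
      intensity = NA_real_)
    prof$intensity[as.integer(rownames(s))] <- s[, 2] / s[, 1]
    om <- tryCatch(orientation_metrics(prof, floor_percentile),
                   error = function(e) NULL)
    if (!is.null(om)) {
      degree[i] <- om$degree; direction[i] <- om$direction
      total[i] <- om$total_intensity; valid[i] <- TRUE
    }
  }
  structure(list(degree = degree, direction = direction, total = total,
                 valid = valid,
                 axes = scan$axes[seq_len(sr)], q_band = q_band),
            class = "orientation_map")
}

#' @export
format.orientation_map <- function(x, ...) {
  sprintf("<orientation_map> %s cells, q band [%g, %g], mean degree %.3f",
          paste(dim(x$degree), collapse = " x "), x$q_band[1], x$q_band[2],
          mean(x$degree, na.rm = TRUE))
}

#' @export
print.orientation_map <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
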