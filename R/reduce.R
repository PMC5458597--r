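#' @importFrom rlang .data
NULL

radial_units <- c("q", "two_theta", "d")

radial_profile <- function(radial, intensity, error, weight, valid,
                           unit = "q") {
  out <- tibble::tibble(radial = radial, intensity = intensity,
                        error = error, weight = weight, valid = valid)
  attr(out, "radial_unit") <- unit
  class(out) <- c("radial_profile", class(out))
  out
}

#' @export
radial_unit <- function(x) attr(x, "radial_unit")

#' Mask out-of-range pixels
#'
#' Adds every pixel with counts below `low` or above `high` to the frame
#' mask (hot / dead / overexposed pixels). Counts are left unchanged.
#'
#' @param frm A [frame()].
#' @param low,high Count bounds, `low < high`.
#' @return The frame with an updated mask.
#' @export
threshold_mask <- function(frm, low, high) {
  stopifnot(inherits(frm, "frame"), low < high)
  bad <- frm$counts < low | frm$counts > high
  frm$mask <- frm$mask | bad
  if (all(frm$mask)) stop("threshold_mask: all pixels masked")
  frm
}

#' Infer count errors from a Poisson model
#'
#' Sets per-pixel errors to `gain * sqrt(max(counts / gain, 1))`: Poisson
#' counting statistics with a floor of one photon, scaled by the detector
#' gain (counts per photon). Existing errors are overwritten; the errors
#' propagate through every downstream step.
#'
#' @param frm A [frame()] with non-negative unmasked counts.
#' @param gain Detector gain, counts per photon (> 0).
#' @return The frame with its `errors` matrix filled in.
#' @export
estimate_errors <- function(frm, gain = 1) {
  stopifnot(inherits(frm, "frame"), gain > 0)
  if (any(frm$counts[!frm$mask] < 0)) {
    stop("estimate_errors: negative unmasked counts")
  }
  frm$errors <- gain * sqrt(pmax(frm$counts / gain, 1))
  frm
}

# solid-angle ratio Omega_0 / Omega_pixel, == 1 at the beam-centre point
solid_angle_factor <- function(geom) {
  B <- detector_basis(geom)
  n <- B[, 3]
  g <- pixel_grid(geom)
  P <- pixel_to_xyz(geom, g$fast, g$slow)
  L2 <- P$x^2 + P$y^2 + P$z^2
  cos_inc <- abs(P$x * n[1] + P$y * n[2] + P$z * n[3]) / sqrt(L2)
  cos_inc_bc <- abs(n[3])
  matrix((L2 / geom$distance^2) * (cos_inc_bc / cos_inc),
         geom$detector$n_slow, geom$detector$n_fast)
}

#' Solid-angle correction
#'
#' Multiplies counts (and errors) by the ratio of the beam-centre pixel's
#' solid angle to each pixel's solid angle
#' (`Omega_pixel = A_pix cos(incidence) / L^2`), so the factor is 1 at the
#' beam centre. For an untilted detector the factor is `1 / cos^3(2 theta)`.
#'
#' @param frm A [frame()].
#' @param geom A [diffraction_geometry()] matching the frame's detector.
#' @return Corrected frame.
#' @export
correct_solid_angle <- function(frm, geom) {
  stopifnot(inherits(frm, "frame"))
  f <- solid_angle_factor(geom)
  frm$counts <- frm$counts * f
  if (!is.null(frm$errors)) frm$errors <- frm$errors * f
  frm
}

# Kahn-convention polarization factor P(two_theta, chi)
polarization_factor <- function(geom, polarization_fraction) {
  g <- pixel_grid(geom)
  P <- pixel_to_xyz(geom, g$fast, g$slow)
  r <- sqrt(P$x^2 + P$y^2 + P$z^2)
  tt <- acos(pmin(1, pmax(-1, P$z / r)))
  chi <- atan2(P$y, P$x)
  pol <- 0.5 * (1 + cos(tt)^2 -
                polarization_fraction * cos(2 * chi) * sin(tt)^2)
  matrix(pol, geom$detector$n_slow, geom$detector$n_fast)
}

#' Polarization correction
#'
#' Divides counts and errors by the Kahn-convention polarization factor
#' `P(2theta, chi) = (1 + cos^2(2theta) - xi cos(2 chi) sin^2(2theta)) / 2`,
#' where `xi` is the polarization fraction of the incident beam. Pixels
#' where `P` vanishes (to within `eps`) are masked instead of divided.
#'
#' @inheritParams correct_solid_angle
#' @param polarization_fraction xi in `[-1, 1]`; 0 for unpolarized,
#'   close to +1 for synchrotron radiation polarized along the fast axis.
#' @param eps Smallest divisor allowed before a pixel is masked.
#' @return Corrected frame.
#' @export
correct_polarization <- function(frm, geom, polarization_fraction = 0,
                                 eps = 1e-9) {
  stopifnot(inherits(frm, "frame"),
            polarization_fraction >= -1, polarization_fraction <= 1)
  pol <- polarization_factor(geom, polarization_fraction)
  sing <- pol < eps
  pol[sing] <- 1
  frm$counts <- frm$counts / pol
  if (!is.null(frm$errors)) frm$errors <- frm$errors / pol
  frm$mask <- frm$mask | sing
  frm
}

#' Normalize a frame by a reference intensity
#'
#' Divides counts and errors by a scalar, by a value stored in the frame
#' metadata (e.g. a monitor reading), or pixelwise by a reference frame.
#' When the reference frame carries errors, relative errors are combined in
#' quadrature.
#'
#' @param frm A [frame()].
#' @param by A nonzero scalar, a metadata key, or a reference [frame()]
#'   nonzero on all unmasked pixels.
#' @return The normalized frame.
#' @export
divide_frame <- function(frm, by) {
  stopifnot(inherits(frm, "frame"))
  if (inherits(by, "frame")) {
    ok <- !frm$mask & !by$mask
    if (any(by$counts[ok] == 0)) stop("divide: reference frame has zeros on unmasked pixels")
    ratio <- frm$counts / by$counts
    if (!is.null(frm$errors) || !is.null(by$errors)) {
      ra <- if (is.null(frm$errors)) 0 else frm$errors / frm$counts
      rb <- if (is.null(by$errors)) 0 else by$errors / by$counts
      frm$errors <- abs(ratio) * sqrt(ra^2 + rb^2)
    }
    frm$counts <- ratio
    frm$mask <- frm$mask | by$mask
    return(frm)
  }
  if (is.character(by)) {
    if (is.null(frm$metadata[[by]])) stop(sprintf("divide: metadata key '%s' missing", by))
    by <- as.numeric(frm$metadata[[by]])
  }
  if (!is.numeric(by) || length(by) != 1 || by == 0) {
    stop("divide: divisor must be a nonzero scalar, metadata key or frame")
  }
  frm$counts <- frm$counts / by
  if (!is.null(frm$errors)) frm$errors <- frm$errors / abs(by)
  frm
}

# moving average; point-reflection padding preserves linear trends at the
# edges (plain reflection would bias sloped profiles by slope * w / 4)
runmean <- function(x, w) {
  w <- max(3L, as.integer(w)); if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  lo <- 2 * x[1] - x[pmin(h:1 + 1L, n)]
  hi <- 2 * x[n] - x[pmax(n - (1:h), 1L)]
  cs <- cumsum(c(0, c(lo, x, hi)))
  (cs[(w + 1):(n + w)] - cs[1:n]) / w
}

#' Dynamic background subtraction
#'
#' Estimates a smooth lower envelope of the radial intensity by iterative
#' clipping: at each iteration the profile is smoothed by a moving average
#' and values exceeding `envelope + clip_factor * local error` are replaced
#' by the envelope. The converged envelope is subtracted. For a frame, the
#' envelope is built on the azimuthally integrated profile and remapped to
#' pixels through each pixel's radial coordinate. Negative results are
#' permitted and errors are left unchanged; `iterations = 0` is the
#' identity.
#'
#' @param x A [frame()] or a radial profile from [integrate_azimuthal()].
#' @param geom Geometry (required for a frame).
#' @param iterations Number of clipping passes.
#' @param clip_factor Clip threshold in units of the local error.
#' @param window Moving-average width in bins (default ~ n/15).
#' @param n_bins Profile resolution used for a frame input.
#' @return Same type as `x`, background-subtracted.
#' @export
subtract_radial_background <- function(x, geom = NULL, iterations = 24,
                                       clip_factor = 3, window = NULL,
                                       n_bins = 512) {
  if (inherits(x, "frame")) {
    if (is.null(geom)) stop("geometry required to subtract background from a frame")
    prof <- integrate_azimuthal(x, geom, n_bins = n_bins, splitting = "none")
    bg <- background_envelope(prof$intensity, prof$error, iterations,
                              clip_factor, window)
    ok <- prof$valid
    qm <- q_map(geom)
    pix_bg <- stats::approx(prof$radial[ok], bg[ok], xout = as.vector(qm),
                            rule = 2)$y
    if (iterations > 0) {
      x$counts <- x$counts - matrix(pix_bg, nrow(x$counts), ncol(x$counts))
    }
    return(x)
  }
  stopifnot(inherits(x, "radial_profile"))
  if (iterations > 0) {
    bg <- background_envelope(x$intensity, x$error, iterations, clip_factor,
                              window)
    x$intensity <- x$intensity - bg
  }
  x
}

# Iteratively clipped smooth lower envelope: values above
# envelope + clip_factor * local error are replaced by the envelope,
# `iterations` times; the converged clip mask (dilated by half a window so
# the bridge anchors on clean background) is then bridged by interpolating
# the smoothed unclipped signal, which removes the residual tent a clipped
# moving average always leaves under broad peaks.
background_envelope <- function(y, err, iterations, clip_factor, window) {
  n <- length(y)
  if (is.null(window)) window <- max(15L, round(n / 10))
  ok <- is.finite(y)
  b <- y; b[!ok] <- stats::median(y[ok])
  if (is.null(err) || all(!is.finite(err)) || all(err[ok] == 0)) {
    err <- rep(stats::mad(diff(b)) / sqrt(2) + 1e-12, n)
  } else {
    err[!is.finite(err)] <- stats::median(err[is.finite(err)])
  }
  s <- b
  for (i in seq_len(max(0L, iterations))) {
    s <- runmean(b, window)
    over <- b > s + clip_factor * err
    b[over] <- s[over]
  }
  mask <- y > s + clip_factor * err
  h <- ceiling(window / 2)
  dm <- as.logical(stats::filter(as.numeric(mask), rep(1, 2 * h + 1),
                                 sides = 2) > 0)
  dm[is.na(dm)] <- mask[is.na(dm)]
  dm <- dm | mask
  s2 <- runmean(b, window)
  # bridge interior masked runs only: a run touching the array boundary
  # has no second anchor and keeps the clipped smooth
  r <- rle(dm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  idx <- seq_len(n)
  for (k in which(r$values)) {
    if (starts[k] == 1 || ends[k] == n) next
    seg <- starts[k]:ends[k]
    s2[seg] <- stats::approx(c(starts[k] - 1, ends[k] + 1),
                             s2[c(starts[k] - 1, ends[k] + 1)],
                             xout = seg)$y
  }
  s2
}

# --- binning machinery -----------------------------------------------------

# expand bbox footprints into (bin, fraction) pairs; lo/hi per pixel
expand_bbox <- function(lo, hi, edges) {
  nb <- length(edges) - 1L
  width <- hi - lo
  ilo <- findInterval(lo, edges, rightmost.closed = TRUE)
  ihi <- findInterval(hi, edges, rightmost.closed = TRUE)
  # clip to in-range part of the footprint
  ilo_c <- pmax(ilo, 1L); ihi_c <- pmin(ihi, nb)
  keep <- which(ihi_c >= ilo_c & width >= 0)
  nspan <- ihi_c[keep] - ilo_c[keep] + 1L
  pix <- rep(keep, nspan)
  bin <- rep(ilo_c[keep], nspan) + sequence(nspan) - 1L
  ov <- pmin(hi[pix], edges[bin + 1L]) - pmax(lo[pix], edges[bin])
  frac <- ifelse(width[pix] > 0, pmax(ov, 0) / width[pix],
                 1)                      # degenerate footprint: whole pixel
  list(pix = pix, bin = bin, frac = frac)
}

accumulate_bins <- function(bin, nb, w, counts, sigma2) {
  wsum <- csum <- e2sum <- numeric(nb)
  s <- rowsum(cbind(w, w * counts, w^2 * sigma2), bin)
  idx <- as.integer(rownames(s))
  wsum[idx] <- s[, 1]; csum[idx] <- s[, 2]; e2sum[idx] <- s[, 3]
  list(wsum = wsum, csum = csum, e2sum = e2sum)
}

#' Azimuthal integration of a 2D frame
#'
#' Reduces a frame to intensity versus a radial coordinate (q, 2-theta or d)
#' by histogramming unmasked pixels into equal-width bins. The bin statistic
#' is the weighted mean `sum(w c) / sum(w)` with propagated error
#' `sqrt(sum(w^2 sigma^2)) / sum(w)`; empty bins are flagged via `valid`,
#' not zero-filled. With `splitting = "none"` each pixel contributes wholly
#' to the bin containing its centre; with `"bbox"` each pixel's radial
#' footprint (the interval spanned by its four corners) is distributed
#' proportionally over the bins it overlaps, conserving total weight.
#'
#' @param frm A [frame()].
#' @param geom A [diffraction_geometry()].
#' @param n_bins Number of radial bins (>= 2).
#' @param radial_unit `"q"` (1/A), `"two_theta"` (deg) or `"d"` (A).
#' @param radial_range Length-2 numeric; default spans the detector.
#' @param azimuth_range Optional chi window in degrees, `c(lo, hi)`; a range
#'   with `lo > hi` wraps across the +/-180 seam.
#' @param splitting `"none"` or `"bbox"`.
#' @return A `radial_profile` tibble: `radial`, `intensity`, `error`,
#'   `weight` (contributing weight per bin), `valid`.
#' @export
integrate_azimuthal <- function(frm, geom, n_bins = 500,
                                radial_unit = c("q", "two_theta", "d"),
                                radial_range = NULL, azimuth_range = NULL,
                                splitting = c("none", "bbox")) {
  radial_unit <- match.arg(radial_unit)
  splitting <- match.arg(splitting)
  stopifnot(inherits(frm, "frame"), n_bins >= 2)
  rmap <- coord_map(geom, radial_unit)
  ok <- !frm$mask & is.finite(rmap)
  if (!is.null(azimuth_range)) {
    chm <- chi_map(geom)
    lo <- azimuth_range[1]; hi <- azimuth_range[2]
    ok <- ok & (if (lo <= hi) chm >= lo & chm <= hi else chm >= lo | chm <= hi)
  }
  if (!any(ok)) stop("integrate_azimuthal: no unmasked pixels selected")
  sel <- which(ok)
  counts <- frm$counts[sel]
  sigma2 <- if (is.null(frm$errors)) rep(0, length(sel)) else frm$errors[sel]^2
  if (splitting == "bbox") {
    cm <- coord_map(geom, radial_unit, corners = TRUE)
    idx <- arrayInd(sel, dim(rmap))
    i <- idx[, 1]; j <- idx[, 2]
    c1 <- cm[cbind(i, j)];     c2 <- cm[cbind(i, j + 1L)]
    c3 <- cm[cbind(i + 1L, j)]; c4 <- cm[cbind(i + 1L, j + 1L)]
    lo <- pmin(c1, c2, c3, c4); hi <- pmax(c1, c2, c3, c4)
    fin <- is.finite(lo) & is.finite(hi)
    if (is.null(radial_range)) radial_range <- range(lo[fin], hi[fin])
  } else {
    if (is.null(radial_range)) radial_range <- range(rmap[sel])
  }
  edges <- seq(radial_range[1], radial_range[2], length.out = n_bins + 1)
  if (splitting == "none") {
    bin <- findInterval(rmap[sel], edges, rightmost.closed = TRUE)
    inb <- bin >= 1L & bin <= n_bins
    acc <- accumulate_bins(bin[inb], n_bins, rep(1, sum(inb)),
                           counts[inb], sigma2[inb])
  } else {
    lo[!fin] <- rmap[sel][!fin]; hi[!fin] <- rmap[sel][!fin]
    ex <- expand_bbox(lo, hi, edges)
    acc <- accumulate_bins(ex$bin, n_bins, ex$frac,
                           counts[ex$pix], sigma2[ex$pix])
  }
  valid <- acc$wsum > 0
  intensity <- ifelse(valid, acc$csum / acc$wsum, NA_real_)
  err <- ifelse(valid, sqrt(acc$e2sum) / acc$wsum, NA_real_)
  radial_profile((edges[-1] + edges[-(n_bins + 1)]) / 2,
                 intensity, err, acc$wsum, valid, radial_unit)
}

#' Cake remapping: azimuth x radial regridding
#'
#' Remaps a frame onto a regular (chi, radial) grid with the same weighted
#' -mean statistic and pixel-splitting options as [integrate_azimuthal()].
#' Collapsing the cake over azimuth with its stored weights (see
#' [collapse_cake()]) reproduces the direct integration for identical
#' binning and splitting.
#'
#' @inheritParams integrate_azimuthal
#' @param n_radial,n_azimuthal Grid size.
#' @param azimuth_range Chi window in degrees, default the full
#'   `(-180, 180]`; `lo > hi` wraps across the seam (handled by rotation).
#' @return A `cake_grid`: azimuth/radial bin centres, intensity, error and
#'   weight matrices of dim `c(n_azimuthal, n_radial)`.
#' @export
cake_remap <- function(frm, geom, n_radial = 500, n_azimuthal = 360,
                       radial_unit = c("q", "two_theta", "d"),
                       radial_range = NULL, azimuth_range = c(-180, 180),
                       splitting = c("none", "bbox")) {
  radial_unit <- match.arg(radial_unit)
  splitting <- match.arg(splitting)
  stopifnot(inherits(frm, "frame"), n_radial >= 2, n_azimuthal >= 1)
  rmap <- coord_map(geom, radial_unit)
  chm <- chi_map(geom)
  ok <- !frm$mask & is.finite(rmap)
  if (!any(ok)) stop("cake_remap: no unmasked pixels")
  # rotate so the requested azimuth window starts at 0
  az0 <- azimuth_range[1]
  span <- azimuth_range[2] - az0
  if (span <= 0) span <- span + 360
  chrot <- (chm - az0) %% 360
  sel <- which(ok & chrot <= span | (ok & chrot == 0))
  chsel <- chrot[sel]
  counts <- frm$counts[sel]
  sigma2 <- if (is.null(frm$errors)) rep(0, length(sel)) else frm$errors[sel]^2
  if (is.null(radial_range)) {
    radial_range <- if (splitting == "bbox") {
      cmr <- coord_map(geom, radial_unit, corners = TRUE)
      range(cmr[is.finite(cmr)])
    } else range(rmap[sel])
  }
  redges <- seq(radial_range[1], radial_range[2], length.out = n_radial + 1)
  aedges <- seq(0, span, length.out = n_azimuthal + 1)
  if (splitting == "none") {
    rbin <- findInterval(rmap[sel], redges, rightmost.closed = TRUE)
    abin <- findInterval(chsel, aedges, rightmost.closed = TRUE)
    abin[chsel == 0] <- 1L   # chi exactly at the rotated seam
    inb <- rbin >= 1L & rbin <= n_radial & abin >= 1L & abin <= n_azimuthal
    cell <- (rbin[inb] - 1L) * n_azimuthal + abin[inb]
    acc <- accumulate_bins(cell, n_radial * n_azimuthal,
                           rep(1, sum(inb)), counts[inb], sigma2[inb])
  } else {
    cmr <- coord_map(geom, radial_unit, corners = TRUE)
    cmc <- (coord_map(geom, "chi", corners = TRUE) - az0) %% 360
    idx <- arrayInd(sel, dim(rmap))
    i <- idx[, 1]; j <- idx[, 2]
    rc <- cbind(cmr[cbind(i, j)], cmr[cbind(i, j + 1L)],
                cmr[cbind(i + 1L, j)], cmr[cbind(i + 1L, j + 1L)])
    cc <- cbind(cmc[cbind(i, j)], cmc[cbind(i, j + 1L)],
                cmc[cbind(i + 1L, j)], cmc[cbind(i + 1L, j + 1L)])
    rlo <- do.call(pmin, as.data.frame(rc)); rhi <- do.call(pmax, as.data.frame(rc))
    bad <- !is.finite(rlo) | !is.finite(rhi)
    rlo[bad] <- rmap[sel][bad]; rhi[bad] <- rmap[sel][bad]
    clo <- do.call(pmin, as.data.frame(cc)); chi_ <- do.call(pmax, as.data.frame(cc))
    # pixels whose corner azimuths straddle the rotated seam
    wraps <- (chi_ - clo) > 180
    exr <- expand_bbox(rlo, rhi, redges)
    pieces <- list()
    norm <- list(lo = clo, hi = chi_, pix = which(!wraps))
    exa_parts <- list()
    if (any(!wraps)) {
      sub <- which(!wraps)
      e <- expand_bbox(clo[sub], chi_[sub], aedges)
      exa_parts[[1]] <- list(pix = sub[e$pix], bin = e$bin, frac = e$frac)
    }
    if (any(wraps)) {
      sub <- which(wraps)
      wlo <- chi_[sub]; whi <- rep(360, length(sub))
      w2lo <- rep(0, length(sub)); w2hi <- clo[sub]
      tot <- (360 - chi_[sub]) + clo[sub]
      e1 <- expand_bbox(wlo, whi, aedges)
      e2 <- expand_bbox(w2lo, w2hi, aedges)
      f1 <- e1$frac * (360 - chi_[sub])[e1$pix] / tot[e1$pix]
      f2 <- e2$frac * clo[sub][e2$pix] / tot[e2$pix]
      exa_parts[[length(exa_parts) + 1]] <-
        list(pix = sub[e1$pix], bin = e1$bin, frac = f1)
      exa_parts[[length(exa_parts) + 1]] <-
        list(pix = sub[e2$pix], bin = e2$bin, frac = f2)
    }
    exa <- list(pix = unlist(lapply(exa_parts, `[[`, "pix")),
                bin = unlist(lapply(exa_parts, `[[`, "bin")),
                frac = unlist(lapply(exa_parts, `[[`, "frac")))
    # cross product of radial and azimuth footprint pieces per pixel
    ra <- split(seq_along(exr$pix), exr$pix)
    aa <- split(seq_along(exa$pix), exa$pix)
    common <- intersect(names(ra), names(aa))
    cellv <- fracv <- pixv <- vector("list", length(common))
    for (k in seq_along(common)) {
      p <- common[k]
      ri <- ra[[p]]; ai <- aa[[p]]
      grid <- expand.grid(ri = ri, ai = ai)
      cellv[[k]] <- (exr$bin[grid$ri] - 1L) * n_azimuthal + exa$bin[grid$ai]
      fracv[[k]] <- exr$frac[grid$ri] * exa$frac[grid$ai]
      pixv[[k]] <- rep(as.integer(p), nrow(grid))
    }
    cell <- unlist(cellv); fr <- unlist(fracv); pixi <- unlist(pixv)
    acc <- accumulate_bins(cell, n_radial * n_azimuthal, fr,
                           counts[pixi], sigma2[pixi])
  }
  dim_ <- c(n_azimuthal, n_radial)
  wsum <- matrix(acc$wsum, dim_[1], dim_[2])
  valid <- wsum > 0
  intensity <- matrix(ifelse(acc$wsum > 0, acc$csum / acc$wsum, NA_real_),
                      dim_[1], dim_[2])
  err <- matrix(ifelse(acc$wsum > 0, sqrt(acc$e2sum) / acc$wsum, NA_real_),
                dim_[1], dim_[2])
  acent <- (aedges[-1] + aedges[-(n_azimuthal + 1)]) / 2 + az0
  acent <- ((acent + 180) %% 360) - 180
  acent[acent == -180] <- 180
  structure(list(azimuth_centres = acent,
                 radial_centres = (redges[-1] + redges[-(n_radial + 1)]) / 2,
                 intensity = intensity, errors = err, weights = wsum,
                 valid = valid, radial_unit = radial_unit),
            class = "cake_grid")
}

#' @export
format.cake_grid <- function(x, ...) {
  sprintf("<cake_grid> %d azimuth x %d radial bins (%s), %d empty cells",
          nrow(x$intensity), ncol(x$intensity), x$radial_unit, sum(!x$valid))
}

#' @export
print.cake_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Collapse a cake over azimuth
#'
#' Weighted collapse of a [cake_remap()] grid over its azimuth rows,
#' reproducing [integrate_azimuthal()] for identical binning and splitting.
#'
#' @param cake A `cake_grid`.
#' @return A `radial_profile`.
#' @export
collapse_cake <- function(cake) {
  stopifnot(inherits(cake, "cake_grid"))
  w <- cake$weights
  iw <- ifelse(cake$valid, cake$intensity * w, 0)
  e2 <- ifelse(cake$valid, (cake$errors * w)^2, 0)
  wsum <- colSums(w)
  valid <- wsum > 0
  radial_profile(cake$radial_centres,
                 ifelse(valid, colSums(iw) / wsum, NA_real_),
                 ifelse(valid, sqrt(colSums(e2)) / wsum, NA_real_),
                 wsum, valid, cake$radial_unit)
}
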