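# Turning ring point sets into a calibrated six-parameter geometry with
# uncertainties: damped least squares on q residuals (auto single-image
# and manual routes) and the algebraic multi-distance solver (semi-major
# axis regressed against known distance increments, eliminating D0 and
# lambda), always polished by the least-squares routine before
# uncertainties are quoted.

.geom_par_names <- c("distance", "beam_centre_fast", "beam_centre_slow",
                     "tilt_pitch", "tilt_yaw", "wavelength")

geom_par_vector <- function(geom) {
  c(distance = geom$distance, beam_centre_fast = geom$beam_centre_fast,
    beam_centre_slow = geom$beam_centre_slow, tilt_pitch = geom$tilt_pitch,
    tilt_yaw = geom$tilt_yaw, wavelength = geom$wavelength)
}

geom_from_par <- function(p, detector) {
  diffraction_geometry(distance = p[["distance"]],
                       beam_centre_fast = p[["beam_centre_fast"]],
                       beam_centre_slow = p[["beam_centre_slow"]],
                       tilt_pitch = p[["tilt_pitch"]],
                       tilt_yaw = p[["tilt_yaw"]],
                       wavelength = p[["wavelength"]],
                       detector = detector)
}

new_calibration_result <- function(geometry, uncertainties, fixed, rms_q,
                                   n_points, n_rings, routine,
                                   calibrant_name) {
  structure(list(geometry = geometry, uncertainties = uncertainties,
                 fixed_parameters = fixed, residual_rms_q = rms_q,
                 n_points = n_points, n_rings = n_rings, routine = routine,
                 calibrant_name = calibrant_name),
            class = "calibration_result")
}

#' @export
format.calibration_result <- function(x, ...) {
  paste0(sprintf("<calibration_result> routine %s, calibrant %s\n",
                 x$routine, x$calibrant_name),
         sprintf("  %s\n", format(x$geometry)),
         sprintf("  residual rms 2pi/d: %.3g 1/A over %d points on %d rings",
                 x$residual_rms_q, x$n_points, x$n_rings))
}

#' @export
print.calibration_result <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) {
  p <- geom_par_vector(x$geometry)
  u <- rep(NA_real_, 6); names(u) <- .geom_par_names
  u[names(x$uncertainties)] <- x$uncertainties
  tibble::tibble(term = .geom_par_names,
                 estimate = unname(p[.geom_par_names]),
                 std_error = unname(u),
                 fixed = .geom_par_names %in% x$fixed_parameters,
                 unit = c("mm", "pixel", "pixel", "deg", "deg", "angstrom"))
}

#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(routine = x$routine, calibrant = x$calibrant_name,
                 residual_rms_q = x$residual_rms_q,
                 n_points = x$n_points, n_rings = x$n_rings,
                 n_free = 6L - length(x$fixed_parameters))
}

# per-point |grad q| (1/A per pixel) used to convert pixel-position
# weights into q weights
q_gradient <- function(geom, fast, slow, h = 0.05) {
  qf1 <- pixel_to_angles(geom, fast + h, slow)$q
  qf0 <- pixel_to_angles(geom, fast - h, slow)$q
  qs1 <- pixel_to_angles(geom, fast, slow + h)$q
  qs0 <- pixel_to_angles(geom, fast, slow - h)$q
  sqrt(((qf1 - qf0) / (2 * h))^2 + ((qs1 - qs0) / (2 * h))^2)
}

refine_core <- function(ring_point_sets, initial, fixed = character(),
                        deltas = NULL, routine = "auto_single",
                        calibrant_name = NA_character_,
                        rel_tol = 1e-10, max_iter = 200L, cond_max = 1e10,
                        trim = TRUE) {
  stopifnot(inherits(initial, "diffraction_geometry"))
  bad <- setdiff(fixed, .geom_par_names)
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  if (is.null(deltas)) deltas <- rep(0, length(ring_point_sets))
  stopifnot(length(deltas) == length(ring_point_sets))
  fast <- unlist(lapply(ring_point_sets, function(s) s$fast))
  slow <- unlist(lapply(ring_point_sets, function(s) s$slow))
  wpx <- unlist(lapply(ring_point_sets, function(s) s$weight))
  dsp <- unlist(lapply(seq_along(ring_point_sets), function(i) {
    rep(attr(ring_point_sets[[i]], "d_spacing"),
        nrow(ring_point_sets[[i]]))
  }))
  dlt <- unlist(lapply(seq_along(ring_point_sets), function(i) {
    rep(deltas[i], nrow(ring_point_sets[[i]]))
  }))
  if (any(!is.finite(dsp))) stop("every ring point set needs a d_spacing")
  n <- length(fast)
  free <- setdiff(.geom_par_names, fixed)
  if (n < 2 + length(free)) {
    stop(sprintf("too few accepted points (%d) for %d free parameters",
                 n, length(free)))
  }
  q_target <- 2 * pi / dsp
  # q weights from pixel-position weights via the local q gradient
  grad <- q_gradient(initial, fast, slow)
  wq <- wpx / pmax(grad, 1e-12)^2          # sigma_q^2 = grad^2 * sigma_px^2
  sw <- sqrt(wq)
  p_full <- geom_par_vector(initial)
  det <- initial$detector
  build_geom <- function(pf) geom_from_par(pf, det)
  resid_fn <- function(pfree) {
    pf <- p_full; pf[free] <- pfree
    if (pf[["distance"]] + min(dlt) <= 0 || pf[["wavelength"]] <= 0) {
      return(rep(1e6, n))
    }
    g <- build_geom(pf)
    qv <- numeric(n)
    for (dl in unique(dlt)) {
      gi <- g; gi$distance <- pf[["distance"]] + dl
      ii <- dlt == dl
      qv[ii] <- pixel_to_angles(gi, fast[ii], slow[ii])$q
    }
    sw * (qv - q_target)
  }
  scale <- c(distance = max(p_full[["distance"]], 1),
             beam_centre_fast = max(det$n_fast / 4, 1),
             beam_centre_slow = max(det$n_slow / 4, 1),
             tilt_pitch = 1, tilt_yaw = 1,
             wavelength = max(p_full[["wavelength"]], 0.01))[free]
  fit <- lm_least_squares(p_full[free], resid_fn, scale = scale,
                          rel_tol = rel_tol, max_iter = max_iter,
                          cond_max = cond_max)
  # one robust trim: profiles that locked onto a neighbouring ring are
  # gross outliers with confident weights; drop > 5 robust sigma and refit
  if (trim) {
    rq <- fit$residuals
    sig <- stats::mad(rq)
    keep_pt <- abs(rq) <= 5 * max(sig, 1e-15)
    if (any(!keep_pt) && sum(keep_pt) >= 2 + length(free) &&
        mean(keep_pt) > 0.5) {
      fast <- fast[keep_pt]; slow <- slow[keep_pt]
      q_target <- q_target[keep_pt]; dlt <- dlt[keep_pt]
      sw <- sw[keep_pt]; n <- length(fast)
      fit <- lm_least_squares(fit$par, resid_fn, scale = scale,
                              rel_tol = rel_tol, max_iter = max_iter,
                              cond_max = cond_max)
    }
  }
  if (!fit$converged) {
    stop(sprintf("geometry refinement did not converge within %d iterations",
                 max_iter))
  }
  if (!is.finite(fit$condition) || fit$condition > cond_max) {
    loading <- free[fit$null_space > 0.3]
    stop(sprintf(paste0("singular normal matrix (condition %.2g): parameters",
                        " {%s} cannot be separated by these rings"),
                 fit$condition, paste(loading, collapse = ", ")))
  }
  p_full[free] <- fit$par
  geom <- build_geom(p_full)
  unc <- sqrt(pmax(diag(fit$cov), 0)); names(unc) <- free
  rms_q <- sqrt(mean((fit$residuals / sw)^2))
  new_calibration_result(geom, unc, fixed, rms_q, n, length(ring_point_sets),
                         routine, calibrant_name)
}

#' Refine the diffraction geometry from ring point sets
#'
#' Minimizes the inverse-variance-weighted sum of squared q residuals,
#' `sum_i w_i (q(point_i; params) - 2 pi / d_i)^2`, over the free geometry
#' parameters by damped least squares (relative tolerance 1e-10, iteration
#' cap 200, internal parameter scaling). Uncertainties come from the
#' covariance of the solution scaled by the reduced chi-square. A singular
#' normal matrix (e.g. the distance-wavelength degeneracy of a single
#' ring) is reported with the offending parameter combination.
#'
#' @param ring_point_sets List of point sets from [extract_ring_points()],
#'   each carrying its `d_spacing`.
#' @param initial Starting [diffraction_geometry()].
#' @param fixed Character vector of parameter names held fixed; the
#'   remaining parameters of `distance`, `beam_centre_fast`,
#'   `beam_centre_slow`, `tilt_pitch`, `tilt_yaw`, `wavelength` are free.
#' @param routine,calibrant_name Bookkeeping recorded on the result.
#' @return A `calibration_result`: geometry, per-free-parameter
#'   uncertainties, `residual_rms_q` (1/A), point/ring counts and the
#'   routine tag. Supports [generics::tidy()] and [generics::glance()].
#' @export
refine_geometry <- function(ring_point_sets, initial, fixed = character(),
                            routine = "manual",
                            calibrant_name = NA_character_) {
  refine_core(ring_point_sets, initial, fixed, routine = routine,
              calibrant_name = calibrant_name)
}

# Assign a list of absolute scattering angles (radians) to calibrant
# d-spacings. Each candidate anchors one of the first angles on one of
# the leading lines, fixing the wavelength through Bragg's law; all
# angles are then matched to the nearest predicted line, the wavelength
# re-estimated over the matches, and the candidate with the most matches
# (ties: smallest relative residual) wins.
assign_tth_to_d <- function(tth, d, wavelength = NULL, max_anchor = 6L,
                            tol_rel = 0.01) {
  score_cand <- function(lam) {
    for (pass in 1:2) {
      reach <- lam < 2 * d
      if (sum(reach) < 2) return(NULL)
      pred <- rep(NA_real_, length(d))
      pred[reach] <- 2 * asin(lam / (2 * d[reach]))
      asg <- vapply(tth, function(t) which.min(abs(pred - t)), 0L)
      err <- abs(pred[asg] - tth)
      ok <- err < tol_rel * tth
      for (j in unique(asg[ok])) {
        ii <- which(asg == j & ok)
        if (length(ii) > 1) ok[ii[-which.min(err[ii])]] <- FALSE
      }
      if (sum(ok) < 2) return(NULL)
      if (is.null(wavelength)) {
        lam <- stats::median(2 * d[asg[ok]] * sin(tth[ok] / 2))
      }
    }
    resid <- sqrt(mean((err[ok] / tth[ok])^2))
    # unmatched predicted lines in the covered span count as missing, but
    # lines closer together than the match resolution are unresolvable:
    # cluster them and count only clusters without any matched member
    span_idx <- which(pred >= 0.98 * min(tth[ok]) &
                      pred <= 1.02 * max(tth[ok]) & is.finite(pred))
    n_missing <- 0L
    if (length(span_idx)) {
      ps <- sort(pred[span_idx], index.return = TRUE)
      newc <- c(TRUE, diff(ps$x) > 2 * tol_rel * ps$x[-1])
      cl <- cumsum(newc)
      matched_line <- unique(asg[ok])
      is_m <- span_idx[ps$ix] %in% matched_line
      n_missing <- length(unique(cl)) - length(unique(cl[is_m]))
    }
    # quality-weighted: a wrong assignment onto a dense line comb matches
    # many angles but only marginally; crisp matches dominate the score
    tolv <- tol_rel * tth[ok]
    quality <- sum(1 - pmin(err[ok] / tolv, 1))
    list(lam = lam, n_ok = sum(ok), resid = resid,
         score = quality - 0.7 * n_missing,
         assignment = ifelse(ok, asg, 0L))
  }
  lams <- if (!is.null(wavelength)) wavelength else {
    unique(unlist(lapply(seq_len(min(3L, length(tth))), function(i0)
      vapply(seq_len(min(max_anchor, length(d))), function(j)
        2 * d[j] * sin(tth[i0] / 2), 0))))
  }
  best <- NULL
  for (lam in lams) {
    cand <- score_cand(lam)
    if (!is.null(cand) &&
        (is.null(best) || cand$score > best$score ||
         (cand$score == best$score && cand$resid < best$resid))) {
      best <- cand
    }
  }
  if (is.null(best) && !is.null(wavelength) && length(tth) == 1) {
    # a single ring with known wavelength assigns directly
    reach <- wavelength < 2 * d
    pred <- rep(NA_real_, length(d))
    pred[reach] <- 2 * asin(wavelength / (2 * d[reach]))
    j <- which.min(abs(pred - tth))
    if (abs(pred[j] - tth) < tol_rel * tth) {
      best <- list(lam = wavelength, n_ok = 1L,
                   resid = abs(pred[j] - tth) / tth, score = 1,
                   assignment = j)
    }
  }
  if (!is.null(best) && is.null(wavelength) && best$n_ok < 2) best <- NULL
  best
}

# Seed the full six-parameter geometry from per-ring ellipse fits: to
# first order in the tilts the ellipse centre drifts from the beam centre
# by D tan^2(2 theta) (sin yaw, cos yaw sin pitch), so regressing ellipse
# centres (mm) on tan^2(2 theta) yields the beam centre (intercept) and
# the tilt direction cosines (slope / D); the distance comes from the
# geometric mean semi-axes. Falls back to the given geometry on failure.
seed_geometry_from_ellipses <- function(sets, initial) {
  det <- initial$detector
  pf <- det$pixel_size_fast; ps <- det$pixel_size_slow
  rows <- list()
  for (s in sets) {
    d <- attr(s, "d_spacing")
    if (!is.finite(d) || nrow(s) < 8) next
    el <- tryCatch(fit_ellipse(cbind(s$fast, s$slow), s$weight),
                   error = function(e) NULL)
    if (is.null(el)) next
    tt <- 2 * asin(initial$wavelength / (2 * d))
    rows[[length(rows) + 1]] <- data.frame(
      u = el$centre_fast * pf, v = el$centre_slow * ps,
      t2 = tan(tt)^2, n_pts = nrow(s),
      D_k = sqrt(el$semi_major * pf * el$semi_minor * ps) / tan(tt))
  }
  if (length(rows) < 2) return(initial)
  df <- do.call(rbind, rows)
  # rings covered only on a partial arc give biased ellipse centres; keep
  # the well-covered rings for the seed regression
  full <- df$n_pts >= 0.6 * max(df$n_pts)
  if (sum(full) >= 2) df <- df[full, ]
  D <- stats::median(df$D_k)
  cu <- stats::coef(stats::lm(u ~ t2, data = df, weights = df$n_pts))
  cv <- stats::coef(stats::lm(v ~ t2, data = df, weights = df$n_pts))
  a3 <- max(-0.25, min(0.25, unname(cu[2]) / D))
  yaw <- -asin(a3)                       # e_fast z-component is -sin(yaw)
  b3 <- max(-0.25, min(0.25, unname(cv[2]) / (D * cos(yaw))))
  pitch <- asin(b3)
  out <- initial
  out$distance <- D
  out$beam_centre_fast <- unname(cu[1]) / pf
  out$beam_centre_slow <- unname(cv[1]) / ps
  out$tilt_pitch <- rad2deg(pitch)
  out$tilt_yaw <- rad2deg(yaw)
  out
}

# A refined geometry whose q residual is comparable to the ring spacing
# means point extraction locked onto the wrong rings (or none): the fit is
# self-consistent garbage and must be reported, not returned.
check_lockon <- function(res, q_rings, counts, route_hint) {
  minsep <- if (length(q_rings) > 1) min(diff(sort(q_rings)))
            else 0.1 * max(q_rings)
  if (res$residual_rms_q > 0.2 * minsep) {
    stop(sprintf(paste0("ring-finding failed (residual %.3g 1/A vs ring ",
                        "spacing %.3g): per-ring accepted points [%s]; %s"),
                 res$residual_rms_q, minsep,
                 paste(counts, collapse = ", "), route_hint))
  }
  invisible(res)
}

# per-ring point extraction given a geometry guess; returns sets + counts.
# The profile window shrinks where neighbouring rings are close, so a
# window never straddles two rings.
extract_rings_for_geometry <- function(frm, geom, rings, n_profiles,
                                       half_width) {
  cons <- lapply(rings$d, function(d)
    tryCatch(predict_ring(geom, d), error = function(e) NULL))
  radii <- vapply(cons, function(cn)
    if (is.null(cn)) NA_real_ else sqrt(cn$semi_major * cn$semi_minor), 0)
  sets <- list(); counts <- integer(nrow(rings))
  for (k in seq_len(nrow(rings))) {
    if (is.null(cons[[k]])) next
    others <- abs(radii[-k] - radii[k])
    gap <- if (any(is.finite(others))) min(others, na.rm = TRUE) else Inf
    hw <- if (is.finite(gap)) max(4, min(half_width, 0.45 * gap)) else half_width
    ps <- tryCatch(
      extract_ring_points(frm, cons[[k]], n_profiles = n_profiles,
                          half_width = hw,
                          d_spacing = rings$d[k], ring_index = rings$ring[k],
                          geom = geom),
      error = function(e) NULL)
    counts[k] <- if (is.null(ps)) 0L else nrow(ps)
    if (!is.null(ps)) sets[[length(sets) + 1]] <- ps
  }
  list(sets = sets, counts = counts)
}

#' Automatic calibration from a single image
#'
#' The automatic route for near-circular rings with the beam centre on the
#' detector: [estimate_initial_rings()] seeds per-ring point extraction,
#' and [refine_geometry()] completes the six-parameter (or
#' wavelength-fixed) solution. With the wavelength free, at least three
#' rings spanning two-theta of 20 degrees are required, otherwise the
#' distance-wavelength ambiguity of Bragg's law at small angles is
#' reported.
#'
#' @param frm A [frame()] of a calibration standard.
#' @param cal A [load_calibrant()].
#' @param detector A [detector_spec()].
#' @param wavelength Known wavelength (Angstrom) to hold fixed, or `NULL`
#'   to determine it.
#' @param n_profiles,half_width Passed to [extract_ring_points()].
#' @return A `calibration_result` with `routine = "auto_single"`.
#' @export
calibrate_auto_single <- function(frm, cal, detector, wavelength = NULL,
                                  n_profiles = 256, half_width = 10) {
  est <- estimate_initial_rings(frm, cal, wavelength = wavelength,
                                detector = detector)
  if (is.null(wavelength)) {
    if (nrow(est$rings) < 3 || max(est$rings$two_theta) < 20) {
      stop(paste0("ambiguity when applying Bragg's law: the wavelength is ",
                  "free but the rings do not span two_theta >= 20 deg over ",
                  ">= 3 rings; fix the wavelength or use more/higher-angle rings"))
    }
  }
  ex <- extract_rings_for_geometry(frm, est$geometry, est$rings,
                                   n_profiles, half_width)
  if (length(ex$sets) < 2) {
    stop(sprintf("ring finding failed: per-ring accepted points [%s]",
                 paste(ex$counts, collapse = ", ")))
  }
  fixed <- if (is.null(wavelength)) character() else "wavelength"
  # circles about a tilt-0 estimate mislead point extraction on tilted
  # detectors (outer-ring windows can lock onto neighbouring rings), so:
  # seed the tilts from the ellipse fits, then re-extract along predicted
  # conics and refine, twice
  geom <- seed_geometry_from_ellipses(ex$sets, est$geometry)
  res <- NULL
  counts_p <- ex$counts
  for (pass in 1:2) {
    rings_p <- ring_positions(cal, geom$wavelength,
                              max(coord_map(geom, "two_theta")))
    ex_p <- extract_rings_for_geometry(frm, geom, rings_p,
                                       n_profiles, half_width)
    if (length(ex_p$sets) < 2) break
    counts_p <- ex_p$counts
    res <- refine_core(ex_p$sets, geom, fixed, routine = "auto_single",
                       calibrant_name = cal$name)
    geom <- res$geometry
  }
  if (is.null(res)) {
    res <- refine_core(ex$sets, geom, fixed, routine = "auto_single",
                       calibrant_name = cal$name)
  }
  check_lockon(res, ring_positions(cal, res$geometry$wavelength,
                                   max(coord_map(res$geometry,
                                                 "two_theta")))$q,
               counts_p,
               "the automatic route assumes near-circular rings with the beam centre on the detector; use the manual route")
  res
}

#' Manual calibration from an initial guess
#'
#' The manual route for large tilts, partial arcs or an off-detector beam
#' centre: rings predicted from the guess seed point extraction on
#' whatever arcs are visible, then [refine_geometry()] completes. If ring
#' finding fails, per-ring acceptance counts are reported so the guess can
#' be adjusted and the routine re-run.
#'
#' @inheritParams calibrate_auto_single
#' @param initial_guess A [diffraction_geometry()] placing the predicted
#'   rings over the measured arcs.
#' @param fixed Parameter names held fixed during refinement.
#' @param rings Optional integer vector selecting calibrant lines.
#' @return A `calibration_result` with `routine = "manual"`.
#' @export
calibrate_manual <- function(frm, cal, initial_guess, fixed = character(),
                             n_profiles = 256, half_width = 10,
                             rings = NULL) {
  ttmax <- max(coord_map(initial_guess, "two_theta"))
  rp <- ring_positions(cal, initial_guess$wavelength, ttmax)
  if (!is.null(rings)) rp <- rp[rp$ring %in% rings, ]
  if (nrow(rp) == 0) stop("no calibrant ring reachable under the initial guess")
  ex <- extract_rings_for_geometry(frm, initial_guess, rp,
                                   n_profiles, half_width)
  if (length(ex$sets) < 2 || sum(ex$counts) < 2 + (6 - length(fixed))) {
    stop(sprintf(paste0("ring-finding failed: per-ring accepted points [%s];",
                        " adjust the initial guess values and re-run"),
                 paste(ex$counts, collapse = ", ")))
  }
  res <- refine_core(ex$sets, initial_guess, fixed, routine = "manual",
                     calibrant_name = cal$name)
  check_lockon(res, rp$q, ex$counts,
               "adjust the initial guess values and re-run")
  res
}

#' Multi-distance calibration
#'
#' The non-iterative algebraic route: from images of the calibrant taken
#' at precisely known increments of the sample-to-detector distance
#' (absolute distance unknown), ellipses are fitted to every ring of every
#' frame; per ring the semi-major axis `a` is regressed against the
#' increment, `a = tan(2 theta) (D0 + delta)`, eliminating both `D0` and
#' the wavelength. Matching the resulting `2 theta` values to calibrant
#' d-spacings then yields the wavelength (if free) and `D0`, and the full
#' six-parameter solution is polished by least squares over all frames
#' jointly before uncertainties are quoted.
#'
#' @param frames List of [frame()]s.
#' @param distance_increments Known increments in mm, same length, all
#'   distinct.
#' @param cal A [load_calibrant()].
#' @param detector A [detector_spec()].
#' @param wavelength Known wavelength (Angstrom) or `NULL` to determine it.
#' @param n_profiles,half_width Passed to [extract_ring_points()].
#' @param max_offset Leading calibrant lines allowed to be absent.
#' @return A `calibration_result` with `routine = "auto_multi"`; the
#'   algebraic intermediates (per-ring slopes/intercepts, pre-polish `D0`
#'   and wavelength) are attached as attribute `"algebraic"`.
#' @export
solve_multi_distance <- function(frames, distance_increments, cal, detector,
                                 wavelength = NULL, n_profiles = 256,
                                 half_width = 10, max_offset = 4L) {
  nF <- length(frames)
  stopifnot(nF >= 2, length(distance_increments) == nF)
  if (anyDuplicated(distance_increments)) {
    stop("distance increments must be distinct")
  }
  # stage 1: per frame, beam centre + detected ring radii (no assignment)
  per_frame <- vector("list", nF)
  for (i in seq_len(nF)) {
    frm <- frames[[i]]
    bc <- estimate_beam_centre(frm$counts, frm$mask)
    opt <- stats::optim(bc, function(p)
      -centre_sharpness(frm$counts, frm$mask, p[1], p[2]),
      method = "Nelder-Mead", control = list(maxit = 200, reltol = 1e-8))
    cf <- opt$par[1]; cs <- opt$par[2]
    prof <- radial_mean_profile(frm$counts, frm$mask, cf, cs)
    radii <- sort(detect_profile_peaks(prof$radius, prof$intensity,
                                       support = prof$n))
    radii <- radii[radii > 5]
    if (length(radii) < 1) stop(sprintf("no rings detected in frame %d", i))
    per_frame[[i]] <- list(centre = c(cf, cs), radii = radii)
  }
  # stage 2: pair rings across frames. Radii of the same ring scale by
  # (D0 + delta_i) / (D0 + delta_ref), so the pairwise radius ratios of
  # true pairs cluster tightly; take the densest ratio cluster as the
  # frame scale, then pair nearest ratios (missing/spurious peaks drop out)
  iref <- which.min(distance_increments)
  r_ref <- per_frame[[iref]]$radii
  pair_idx <- matrix(NA_integer_, nF, length(r_ref))
  pair_idx[iref, ] <- seq_along(r_ref)
  for (i in seq_len(nF)) {
    if (i == iref) next
    ri <- per_frame[[i]]$radii
    ratios <- as.vector(outer(ri, r_ref, "/"))
    counts_in <- vapply(ratios, function(s)
      sum(abs(ratios / s - 1) < 0.01), 0L)
    s_i <- stats::median(ratios[abs(ratios / ratios[which.max(counts_in)] - 1)
                                < 0.01])
    for (b in seq_along(r_ref)) {
      a <- which.min(abs(ri / s_i - r_ref[b]))
      if (abs(ri[a] / s_i - r_ref[b]) < 0.02 * r_ref[b]) pair_idx[i, b] <- a
    }
  }
  keep_ring <- which(colSums(!is.na(pair_idx)) == nF)
  if (length(keep_ring) < 1) stop("no ring could be tracked across all frames")
  # stage 3: ellipse fit per tracked ring per frame
  px <- (detector$pixel_size_fast + detector$pixel_size_slow) / 2
  m <- length(keep_ring)
  A <- matrix(NA_real_, nF, m)
  points_by <- vector("list", nF * m); dim(points_by) <- c(nF, m)
  for (i in seq_len(nF)) {
    cen <- per_frame[[i]]$centre
    frm <- frames[[i]]
    rall <- per_frame[[i]]$radii
    for (k in seq_len(m)) {
      r0 <- rall[pair_idx[i, keep_ring[k]]]
      gap <- min(abs(rall[rall != r0] - r0), Inf)
      hw <- max(4, min(half_width, 0.45 * gap))
      ps <- tryCatch(extract_ring_points(
        frm, conic(cen[1], cen[2], r0, r0, 0), n_profiles, hw,
        d_spacing = NA_real_), error = function(e) NULL)
      el <- if (is.null(ps)) NULL else
        tryCatch(fit_ellipse(cbind(ps$fast, ps$slow), ps$weight),
                 error = function(e) NULL)
      if (!is.null(el)) { A[i, k] <- el$semi_major * px; points_by[[i, k]] <- ps }
    }
  }
  ok_ring <- which(colSums(!is.na(A)) == nF)
  if (length(ok_ring) < 1) stop("no ring could be ellipse-fitted across all frames")
  A <- A[, ok_ring, drop = FALSE]
  points_by <- points_by[, ok_ring, drop = FALSE]
  m <- length(ok_ring)
  # stage 4: per ring, semi-major axis vs increment eliminates D0 and
  # wavelength: slope = tan(2 theta), intercept / slope = D0
  slopes <- intercepts <- numeric(m)
  for (k in seq_len(m)) {
    co <- stats::coef(stats::lm(A[, k] ~ distance_increments))
    intercepts[k] <- co[1]; slopes[k] <- co[2]
  }
  if (any(slopes <= 0)) {
    stop("regression of semi-major axis on increment has non-positive slope")
  }
  D0_rings <- intercepts / slopes
  D0 <- stats::median(D0_rings)
  tth <- atan(slopes)          # slope = tan(2 theta)
  # stage 5: assign the regressed absolute 2 theta values to calibrant
  # lines. Unlike radius ratios (degenerate at high energy), the absolute
  # angles fix the wavelength per anchor; the assignment whose implied
  # wavelength is consistent across rings wins.
  best <- assign_tth_to_d(tth, cal$d_spacings, wavelength,
                          max_anchor = max_offset + 2L)
  if (is.null(best)) {
    stop("no d-spacing assignment consistent across rings")
  }
  keep <- which(best$assignment > 0)
  dd <- cal$d_spacings[best$assignment[keep]]
  centre <- colMeans(do.call(rbind, lapply(per_frame, `[[`, "centre")))
  init <- diffraction_geometry(distance = D0, beam_centre_fast = centre[1],
                               beam_centre_slow = centre[2],
                               tilt_pitch = 0, tilt_yaw = 0,
                               wavelength = best$lam, detector = detector)
  sets <- list(); deltas <- numeric(0)
  for (i in seq_len(nF)) {
    for (j in seq_along(keep)) {
      ps <- points_by[[i, keep[j]]]
      if (is.null(ps)) next
      attr(ps, "d_spacing") <- dd[j]
      attr(ps, "ring_index") <- best$assignment[keep[j]]
      sets[[length(sets) + 1]] <- ps
      deltas <- c(deltas, distance_increments[i])
    }
  }
  fixed <- if (is.null(wavelength)) character() else "wavelength"
  res <- refine_core(sets, init, fixed, deltas = deltas,
                     routine = "auto_multi", calibrant_name = cal$name)
  # polish pass: re-extract every ring of every frame along the refined
  # conics (q-space profile fits) and re-refine jointly
  sets2 <- list(); deltas2 <- numeric(0)
  for (i in seq_len(nF)) {
    gi <- res$geometry
    gi$distance <- res$geometry$distance + distance_increments[i]
    rp <- ring_positions(cal, gi$wavelength,
                         max(coord_map(gi, "two_theta")))
    ex_i <- extract_rings_for_geometry(frames[[i]], gi, rp,
                                       n_profiles, half_width)
    for (ps in ex_i$sets) {
      sets2[[length(sets2) + 1]] <- ps
      deltas2 <- c(deltas2, distance_increments[i])
    }
  }
  if (length(sets2) >= 2) {
    res <- refine_core(sets2, res$geometry, fixed, deltas = deltas2,
                       routine = "auto_multi", calibrant_name = cal$name)
  }
  attr(res, "algebraic") <- list(slopes = slopes, intercepts = intercepts,
                                 D0_rings = D0_rings, D0 = D0,
                                 wavelength = best$lam,
                                 semi_major_mm = A,
                                 two_theta = rad2deg(tth))
  res
}
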