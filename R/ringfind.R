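# Locating Debye-Scherrer rings: approximate geometry from a radial
# profile, sub-pixel ring points from Gaussian fits to radial line
# profiles ("several hundred line profiles across each circumference"),
# and a numerically stable direct least-squares ellipse fit.

bilinear_sample <- function(img, mask, fast, slow) {
  ns <- nrow(img); nf <- ncol(img)
  j0 <- floor(fast); i0 <- floor(slow)
  fj <- fast - j0; fi <- slow - i0
  ok <- j0 >= 0 & j0 <= nf - 2 & i0 >= 0 & i0 <= ns - 2
  out <- rep(NA_real_, length(fast))
  if (any(ok)) {
    i <- i0[ok] + 1L; j <- j0[ok] + 1L
    v00 <- img[cbind(i, j)];     v01 <- img[cbind(i, j + 1L)]
    v10 <- img[cbind(i + 1L, j)]; v11 <- img[cbind(i + 1L, j + 1L)]
    m <- mask[cbind(i, j)] | mask[cbind(i, j + 1L)] |
         mask[cbind(i + 1L, j)] | mask[cbind(i + 1L, j + 1L)]
    v <- v00 * (1 - fi[ok]) * (1 - fj[ok]) + v01 * (1 - fi[ok]) * fj[ok] +
         v10 * fi[ok] * (1 - fj[ok]) + v11 * fi[ok] * fj[ok]
    v[m] <- NA_real_
    out[ok] <- v
  }
  out
}

# Gaussian + linear baseline fit to a 1D profile; analytic jacobian.
# Returns NULL when the fit cannot be attempted.
fit_gaussian_linear <- function(x, y) {
  ok <- is.finite(y)
  if (sum(ok) < 6) return(NULL)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  base0 <- (y[1] + y[n]) / 2
  slope0 <- (y[n] - y[1]) / (x[n] - x[1])
  amp0 <- max(y) - base0
  c0 <- x[which.max(y)]
  s0 <- diff(range(x)) / 8
  if (!is.finite(amp0) || amp0 <= 0) amp0 <- max(abs(y - base0), 1e-6)
  model <- function(p, xx) {
    p[1] * exp(-(xx - p[2])^2 / (2 * p[3]^2)) + p[4] + p[5] * (xx - x[1])
  }
  fn <- function(p) model(p, x) - y
  jac <- function(p) {
    e <- exp(-(x - p[2])^2 / (2 * p[3]^2))
    cbind(e,
          p[1] * e * (x - p[2]) / p[3]^2,
          p[1] * e * (x - p[2])^2 / p[3]^3,
          1,
          x - x[1])
  }
  p0 <- c(amp0, c0, s0, base0, slope0)
  sc <- c(max(abs(amp0), 1), diff(range(x)), diff(range(x)) / 4,
          max(abs(base0), 1), max(abs(slope0), 0.1))
  fit <- tryCatch(
    lm_least_squares(p0, fn, jac = jac, scale = sc, rel_tol = 1e-12,
                     max_iter = 100L),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  rms <- sqrt(mean(fit$residuals^2))
  centre_var <- if (!is.null(fit$cov)) fit$cov[2, 2] else NA_real_
  list(amplitude = p[1], centre = p[2], sigma = abs(p[3]),
       baseline_offset = p[4], baseline_slope = p[5],
       rms_residual = rms, centre_var = centre_var,
       converged = fit$converged)
}

#' Extract sub-pixel ring points along a predicted conic
#'
#' Takes `n_profiles` radial line profiles across the ring circumference
#' (rays from the conic centre through equally spaced points on the
#' predicted ellipse), samples each by bilinear interpolation at unit-pixel
#' steps over `+/- half_width` about the predicted ring radius, and fits a
#' Gaussian peak with linear baseline to each. Accepted fits (amplitude
#' above `accept_snr` times the fit residual, centre inside the middle 80%
#' of the window, not on masked pixels) become weighted sub-pixel points;
#' partial arcs are handled naturally because off-detector or masked
#' profiles are simply rejected.
#'
#' @param frm A [frame()].
#' @param predicted A [conic()] close to the true ring.
#' @param n_profiles Number of line profiles around the circumference.
#' @param half_width Half-width of the profile window in pixels.
#' @param accept_snr Amplitude acceptance threshold, in units of the
#'   per-profile rms fit residual.
#' @param d_spacing,ring_index Optional bookkeeping carried on the result.
#' @param geom Optional [diffraction_geometry()]; when given, each profile
#'   is fitted as a Gaussian in q (the physical ring model) instead of in
#'   the spatial coordinate, removing the q-curvature bias at high angles.
#' @return A `ring_point_set`: tibble of `fast`, `slow`, `weight`
#'   (inverse variance of the fitted centre) with attributes `d_spacing`
#'   and `ring_index`; at least 6 points, otherwise an error.
#' @export
extract_ring_points <- function(frm, predicted, n_profiles = 256,
                                half_width = 10, accept_snr = 3,
                                d_spacing = NA_real_, ring_index = NA_integer_,
                                geom = NULL) {
  stopifnot(inherits(frm, "frame"), inherits(predicted, "conic"))
  ns <- nrow(frm$counts); nf <- ncol(frm$counts)
  t_par <- seq(0, 2 * pi, length.out = n_profiles + 1)[-(n_profiles + 1)]
  pts <- conic_points(predicted, t_par)
  # cross the ring along the local ellipse normal (a ray from the centre
  # crosses obliquely on eccentric rings, widening and biasing profiles)
  th <- predicted$orientation * pi / 180
  txe <- -predicted$semi_major * sin(t_par)   # tangent in ellipse frame
  tye <- predicted$semi_minor * cos(t_par)
  tx <- txe * cos(th) - tye * sin(th)
  ty <- txe * sin(th) + tye * cos(th)
  tl <- sqrt(tx^2 + ty^2)
  ux <- ty / tl; uy <- -tx / tl               # normal
  dx <- pts$fast - predicted$centre_fast
  dy <- pts$slow - predicted$centre_slow
  flip <- ux * dx + uy * dy < 0               # orient outward
  ux[flip] <- -ux[flip]; uy[flip] <- -uy[flip]
  r0 <- sqrt(dx^2 + dy^2)
  on_det <- pts$fast >= -half_width & pts$fast <= nf - 1 + half_width &
            pts$slow >= -half_width & pts$slow <= ns - 1 + half_width
  if (!any(on_det)) {
    stop("extract_ring_points: predicted conic lies entirely off the detector")
  }
  steps <- seq(-half_width, half_width, by = 1)
  res_f <- res_s <- res_w <- numeric(0)
  n_try <- 0L
  for (k in which(on_det)) {
    fx <- pts$fast[k] + steps * ux[k]
    sx <- pts$slow[k] + steps * uy[k]
    prof <- bilinear_sample(frm$counts, frm$mask, fx, sx)
    if (sum(is.finite(prof)) < max(7, length(steps) * 0.6)) next
    n_try <- n_try + 1L
    if (!is.null(geom)) {
      # fit in q: the physical ring profile is a function of momentum
      # transfer, so fitting in the spatial coordinate is biased by the
      # curvature of q(s) at high angles
      qv <- pixel_to_angles(geom, fx, sx)$q
      dq <- diff(qv)
      if (!(all(dq > 0) || all(dq < 0))) next   # q not monotone here
      fit <- fit_gaussian_linear(qv, prof)
      if (is.null(fit)) next
      if (!(fit$amplitude > accept_snr * max(fit$rms_residual, 1e-15))) next
      qlo <- min(qv) + 0.1 * diff(range(qv))
      qhi <- max(qv) - 0.1 * diff(range(qv))
      if (fit$centre < qlo || fit$centre > qhi) next
      if (!is.finite(fit$sigma) || fit$sigma <= 0) next
      s_star <- stats::approx(qv, steps, xout = fit$centre)$y
      if (!is.finite(s_star)) next
      a_loc <- abs(diff(range(qv)) / diff(range(steps)))
      w <- if (is.finite(fit$centre_var) && fit$centre_var > 0) {
        a_loc^2 / fit$centre_var
      } else {
        1 / (0.05^2)
      }
      pf <- pts$fast[k] + s_star * ux[k]
      psl <- pts$slow[k] + s_star * uy[k]
    } else {
      fit <- fit_gaussian_linear(steps, prof)
      if (is.null(fit)) next
      inner <- 0.8 * half_width
      if (!(fit$amplitude > accept_snr * max(fit$rms_residual, 1e-12))) next
      if (abs(fit$centre) > inner) next
      if (!is.finite(fit$sigma) || fit$sigma <= 0) next
      pf <- pts$fast[k] + fit$centre * ux[k]
      psl <- pts$slow[k] + fit$centre * uy[k]
      w <- if (is.finite(fit$centre_var) && fit$centre_var > 0) {
        1 / fit$centre_var
      } else {
        1 / (0.05^2)   # noiseless profiles: centre variance ~ numerical only
      }
    }
    if (pf < 0 || pf > nf - 1 || psl < 0 || psl > ns - 1) next
    if (frm$mask[round(psl) + 1, round(pf) + 1]) next
    res_f <- c(res_f, pf); res_s <- c(res_s, psl); res_w <- c(res_w, w)
  }
  if (length(res_f) < 6) {
    stop(sprintf("extract_ring_points: only %d of %d profiles accepted (>= 6 required); adjust the initial guess",
                 length(res_f), n_profiles))
  }
  out <- tibble::tibble(fast = res_f, slow = res_s, weight = res_w)
  attr(out, "d_spacing") <- d_spacing
  attr(out, "ring_index") <- ring_index
  attr(out, "n_profiles") <- n_profiles
  class(out) <- c("ring_point_set", class(out))
  out
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D points by the numerically stable direct algebraic
#' method (ellipse-specific constraint `4AC - B^2 = 1`, Halir-Flusser
#' formulation) after centring/scaling normalization for conditioning.
#' Exact for noiseless points on an ellipse.
#'
#' @param points Two-column matrix / data frame (`fast`, `slow`) of at
#'   least 6 non-degenerate points.
#' @param weights Optional positive weights (inverse variances).
#' @return A [conic()].
#' @export
fit_ellipse <- function(points, weights = NULL) {
  pts <- as.matrix(points[, 1:2])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 6) stop("fit_ellipse: at least 6 points required")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  sc <- mean(sqrt((pts[, 1] - mx)^2 + (pts[, 2] - my)^2))
  if (!is.finite(sc) || sc <= 0) stop("fit_ellipse: degenerate points")
  x <- (pts[, 1] - mx) / sc; y <- (pts[, 2] - my) / sc
  sw <- sqrt(weights)
  D1 <- cbind(x^2, x * y, y^2) * sw
  D2 <- cbind(x, y, 1) * sw
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("fit_ellipse: degenerate point configuration (collinear?)")
  })
  M <- S1 + S2 %*% T3
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  good <- which(cond > 0)
  if (length(good) == 0) stop("fit_ellipse: best-fitting conic is not an ellipse")
  a1 <- evec[, good[which.max(Re(ev$values)[good] * 0 + 1)]]
  a1 <- evec[, good[1]]
  co_n <- c(a1, as.vector(T3 %*% a1))   # conic in normalized coords
  # denormalize: x_n = (x - mx)/sc
  A <- co_n[1] / sc^2
  B <- co_n[2] / sc^2
  C <- co_n[3] / sc^2
  D <- co_n[4] / sc - 2 * A * mx - B * my
  E <- co_n[5] / sc - 2 * C * my - B * mx
  F <- co_n[6] + A * mx^2 + B * mx * my + C * my^2 -
       co_n[4] * mx / sc - co_n[5] * my / sc
  conic_from_coeffs(c(A, B, C, D, E, F))
}

# peak detection on a 1D radial profile: local maxima above a running
# baseline, refined by 3-point parabolic interpolation
detect_profile_peaks <- function(r, y, min_prominence = NULL,
                                 support = NULL, min_support = 40) {
  if (!is.null(support)) y[!is.na(support) & support < min_support] <- NA
  ok <- is.finite(y)
  ys <- y; ys[!ok] <- stats::median(y[ok])
  base <- runmean(stats::runmed(ys, min(31L, (length(ys) %/% 2) * 2 - 1)), 15)
  resid <- ys - base
  if (is.null(min_prominence)) {
    min_prominence <- max(5 * stats::mad(resid, na.rm = TRUE), 1e-9)
  }
  n <- length(ys)
  thresh <- rep(min_prominence, n)
  if (!is.null(support)) {
    # Poisson-ish noise floor of a bin mean shrinks with pixel support
    sigma_bin <- sqrt(pmax(base, 1) / pmax(support, 1))
    sigma_bin[!is.finite(sigma_bin)] <- Inf
    thresh <- pmax(thresh, 4 * sigma_bin)
  }
  idx <- which(resid > thresh)
  idx <- idx[idx > 2 & idx < n - 1]
  idx <- idx[ys[idx] >= ys[idx - 1] & ys[idx] >= ys[idx + 1] &
             ys[idx] > ys[pmax(idx - 2, 1)] & ys[idx] > ys[pmin(idx + 2, n)]]
  if (length(idx) == 0) return(numeric(0))
  # merge maxima closer than 3 bins, keep the taller
  keep <- logical(length(idx))
  ordh <- order(-ys[idx])
  taken <- rep(FALSE, n)
  for (k in ordh) {
    i <- idx[k]
    if (!any(taken[max(1, i - 3):min(n, i + 3)])) { keep[k] <- TRUE; taken[i] <- TRUE }
  }
  idx <- sort(idx[keep])
  vapply(idx, function(i) {
    y1 <- ys[i - 1]; y2 <- ys[i]; y3 <- ys[i + 1]
    den <- (y1 - 2 * y2 + y3)
    off <- if (den != 0) 0.5 * (y1 - y3) / den else 0
    r[i] + off * (r[2] - r[1])
  }, 0)
}

# radial mean profile about a centre, 1-px bins, with per-bin pixel support
radial_mean_profile <- function(counts, mask, cf, cs) {
  ns <- nrow(counts); nf <- ncol(counts)
  jj <- matrix(seq_len(nf) - 1, ns, nf, byrow = TRUE)
  ii <- matrix(seq_len(ns) - 1, ns, nf)
  r <- sqrt((jj - cf)^2 + (ii - cs)^2)
  ok <- !mask
  bin <- floor(r[ok]) + 1L
  s <- rowsum(cbind(1, counts[ok]), bin)
  rr <- as.integer(rownames(s))
  prof <- nn <- rep(NA_real_, max(rr))
  prof[rr] <- s[, 2] / s[, 1]
  nn[rr] <- s[, 1]
  tibble::tibble(radius = seq_along(prof) - 0.5, intensity = prof,
                 n = nn)
}

# Beam-centre estimate from intensity symmetry: the autoconvolution of the
# background-subtracted image peaks at twice the symmetry centre (robust to
# rings clipped by the detector edge, unlike a plain centroid). The mod-N
# ambiguity of the FFT leaves <= 4 candidates; the sharpest radial profile
# decides.
estimate_beam_centre <- function(counts, mask, centre = NULL,
                                 r_cut = NULL) {
  w <- counts - stats::median(counts[!mask])
  w[w < 0] <- 0
  w[mask] <- 0
  if (!is.null(centre) && !is.null(r_cut) && is.finite(r_cut)) {
    # restrict to the inner rings: at high 2 theta x tilt the pattern is
    # no longer centro-symmetric about the beam centre (ellipse centres
    # drift one way), which biases the full-image symmetry estimate
    jj <- matrix(seq_len(ncol(w)) - 1, nrow(w), ncol(w), byrow = TRUE)
    ii <- matrix(seq_len(nrow(w)) - 1, nrow(w), ncol(w))
    w[(jj - centre[1])^2 + (ii - centre[2])^2 > r_cut^2] <- 0
    if (all(w == 0)) return(centre)
  }
  Fw <- stats::fft(w)
  conv <- Re(stats::fft(Fw * Fw, inverse = TRUE))
  u <- arrayInd(which.max(conv), dim(w)) - 1L   # (slow, fast), 0-based
  ns <- nrow(w); nf <- ncol(w)
  cand_s <- unique(pmin(pmax(c(u[1] / 2, (u[1] + ns) / 2), 0), ns - 1))
  cand_f <- unique(pmin(pmax(c(u[2] / 2, (u[2] + nf) / 2), 0), nf - 1))
  best <- NULL
  for (cs in cand_s) for (cf in cand_f) {
    s <- centre_sharpness(counts, mask, cf, cs)
    if (is.null(best) || s > best$s) best <- list(cf = cf, cs = cs, s = s)
  }
  c(best$cf, best$cs)
}

# sharpness objective for beam-centre refinement: variance of the radial
# profile about its smooth baseline (rings smear out when the centre is off)
centre_sharpness <- function(counts, mask, cf, cs, stride = NULL) {
  if (is.null(stride)) stride <- max(1L, floor(min(dim(counts)) / 512))
  if (stride > 1L) {
    si <- seq(1L, nrow(counts), by = stride)
    sj <- seq(1L, ncol(counts), by = stride)
    counts <- counts[si, sj]; mask <- mask[si, sj]
    cf <- cf / stride; cs <- cs / stride
  }
  prof <- radial_mean_profile(counts, mask, cf, cs)
  y <- prof$intensity
  ok <- is.finite(y)
  if (sum(ok) < 20) return(0)
  y <- y[ok]
  sum((y - runmean(y, 15))^2)
}

# Assign detected ring radii (mm) to calibrant d-spacings. Each candidate
# anchors the first detected radius on a calibrant line (and, when the
# wavelength is free, the second radius on a later line, solving for the
# wavelength through the radius ratio); all radii are then matched to the
# nearest predicted ring, the distance re-estimated by least squares over
# the matches, and the assignment with the most matches (ties: smallest
# residual) wins. Gaps (undetected or extra peaks) are tolerated.
match_rings_to_d <- function(r_mm, d, wavelength = NULL, px,
                             max_anchor = 5L, tol_rel = 0.012,
                             max_radii = 4L) {
  # outer-ring radii are increasingly distorted by the tilt-driven drift
  # of ellipse centres (~ tan^2(2 theta)); match on the inner radii only
  r_all <- r_mm
  r_mm <- r_mm[seq_len(min(max_radii, length(r_mm)))]
  score_candidate <- function(D, lam) {
    reach <- lam < 2 * d
    if (sum(reach) < 2 || D <= 0) return(NULL)
    tth <- rep(NA_real_, length(d))
    tth[reach] <- tan(2 * asin(lam / (2 * d[reach])))
    pred <- D * tth
    asg <- vapply(r_mm, function(r) which.min(abs(pred - r)), 0L)
    err <- abs(pred[asg] - r_mm)
    ok <- err < pmax(tol_rel * r_mm, 2 * px)
    # keep the best detected radius when two claim the same line
    for (j in unique(asg[ok])) {
      ii <- which(asg == j & ok)
      if (length(ii) > 1) ok[ii[-which.min(err[ii])]] <- FALSE
    }
    if (sum(ok) < 2) return(NULL)
    t_ok <- tth[asg[ok]]
    D2 <- sum(r_mm[ok] * t_ok) / sum(t_ok^2)
    resid <- sqrt(mean((r_mm[ok] - D2 * t_ok)^2))
    # penalize predicted rings inside the covered radial span that have no
    # detected counterpart: a wrong (too dense) assignment explains the
    # detected radii but predicts many rings that are absent
    pred2 <- D2 * tth
    span <- pred2 >= 0.95 * min(r_mm[ok]) & pred2 <= 1.02 * max(r_mm[ok]) &
            is.finite(pred2)
    n_missing <- sum(span) - length(unique(asg[ok]))
    list(D = D2, lam = lam, n_ok = sum(ok), resid = resid,
         score = sum(ok) - 0.7 * n_missing,
         assignment = ifelse(ok, asg, 0L))
  }
  best <- NULL
  consider <- function(cand) {
    if (!is.null(cand) &&
        (is.null(best) || cand$score > best$score ||
         (cand$score == best$score && cand$resid < best$resid))) {
      best <<- cand
    }
  }
  n_anchor <- min(max_anchor, length(d))
  anchors <- seq_len(min(3L, length(r_mm)))   # tolerate spurious low-r peaks
  if (!is.null(wavelength)) {
    reach <- which(wavelength < 2 * d)
    for (i0 in anchors) {
      for (j in utils::head(reach, n_anchor)) {
        D <- r_mm[i0] / tan(2 * asin(wavelength / (2 * d[j])))
        consider(score_candidate(D, wavelength))
      }
    }
  } else {
    if (length(r_mm) < 2) return(NULL)
    for (i0 in anchors) {
      if (i0 + 1 > length(r_mm)) next
      ratio <- r_mm[i0 + 1] / r_mm[i0]
      for (j in seq_len(n_anchor)) {
        for (k in (j + 1):min(j + n_anchor, length(d))) {
          # solve tan(2 asin(lam/2 d_k)) / tan(2 asin(lam/2 d_j)) = ratio
          f <- function(lam) {
            tan(2 * asin(lam / (2 * d[k]))) /
              tan(2 * asin(lam / (2 * d[j]))) - ratio
          }
          up <- 2 * d[k] * 0.999
          lo <- up * 1e-4
          if (f(lo) * f(up) > 0) next
          lam <- tryCatch(stats::uniroot(f, c(lo, up), tol = 1e-12)$root,
                          error = function(e) NULL)
          if (is.null(lam)) next
          D <- r_mm[i0] / tan(2 * asin(lam / (2 * d[j])))
          consider(score_candidate(D, lam))
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  # final pass: assign the full detected list at the selected (D, lambda),
  # with a drift-tolerant window, so downstream extraction can seed from
  # every identified ring
  reach <- best$lam < 2 * d
  tth <- rep(NA_real_, length(d))
  tth[reach] <- tan(2 * asin(best$lam / (2 * d[reach])))
  pred <- best$D * tth
  asg <- vapply(r_all, function(r) which.min(abs(pred - r)), 0L)
  err <- abs(pred[asg] - r_all)
  ok <- err < pmax(0.025 * r_all, 2 * px)
  for (j in unique(asg[ok])) {
    ii <- which(asg == j & ok)
    if (length(ii) > 1) ok[ii[-which.min(err[ii])]] <- FALSE
  }
  best$assignment <- ifelse(ok, asg, 0L)
  best$n_ok <- sum(ok)
  best
}

#' Approximate geometry from a single ring image
#'
#' The automatic route's first stage: assumes near-circular rings with the
#' beam centre on the detector (the documented applicability limit).
#' Estimates the beam centre (from the supplied guess, or the intensity
#' centroid refined by maximizing radial-profile sharpness), azimuthally
#' averages about it, detects ring radii as profile peaks, and assigns the
#' radii to calibrant d-spacings by finding the assignment most consistent
#' with a single distance (and wavelength, when free), via least squares
#' over `r = D tan(2 theta)`.
#'
#' @param frm A [frame()].
#' @param cal A [load_calibrant()].
#' @param wavelength Known wavelength in Angstrom, or `NULL` to estimate it
#'   together with the distance.
#' @param beam_centre_guess Optional `c(fast, slow)` starting centre.
#' @param detector Optional [detector_spec()] (defaults to square 0.2 mm
#'   pixels matching the frame).
#' @param max_offset Largest leading calibrant lines allowed to be missing
#'   from the image.
#' @return A list: `geometry` (tilt-0 [diffraction_geometry()] estimate),
#'   `rings` (tibble of `ring`, `d`, `radius_px`, `two_theta`), `profile`
#'   (radial mean profile tibble).
#' @export
estimate_initial_rings <- function(frm, cal, wavelength = NULL,
                                   beam_centre_guess = NULL, detector = NULL,
                                   max_offset = 4L) {
  stopifnot(inherits(frm, "frame"), inherits(cal, "calibrant"))
  ns <- nrow(frm$counts); nf <- ncol(frm$counts)
  if (is.null(detector)) detector <- detector_spec(ns, nf, 0.2)
  counts <- frm$counts; counts[frm$mask] <- NA
  if (is.null(beam_centre_guess)) {
    if (all(counts[!frm$mask] <= stats::median(counts, na.rm = TRUE))) {
      stop("no rings detected: image has no intensity above median")
    }
    bc <- estimate_beam_centre(frm$counts, frm$mask)
    cf <- bc[1]; cs <- bc[2]
  } else {
    cf <- beam_centre_guess[1]; cs <- beam_centre_guess[2]
  }
  # NOTE: no sharpness-based Nelder-Mead polish here. The sharpness
  # optimum is the mean-ellipse-centre compromise, biased away from the
  # beam centre on tilted detectors (especially with clipped rings); the
  # symmetry centre plus the innermost-ring ellipse refinement below is
  # unbiased.
  if (cf < 0 || cf > nf - 1 || cs < 0 || cs > ns - 1) {
    stop("estimated beam centre lies off the detector; use the manual route")
  }
  prof <- radial_mean_profile(frm$counts, frm$mask, cf, cs)
  radii <- detect_profile_peaks(prof$radius, prof$intensity,
                                support = prof$n)
  radii <- radii[radii > 5]
  if (length(radii) < 2) {
    stop(sprintf("no rings detected: %d radial peaks found (>= 2 required)",
                 length(radii)))
  }
  # refine the symmetry centre on the inner rings only, where the
  # tilt-driven drift of ellipse centres is negligible, then re-profile
  if (is.null(beam_centre_guess)) {
    r_cut <- 1.3 * sort(radii)[min(2L, length(radii))]
    bc2 <- estimate_beam_centre(frm$counts, frm$mask, centre = c(cf, cs),
                                r_cut = r_cut)
    if (max(abs(bc2 - c(cf, cs))) >= 1) {
      cf <- bc2[1]; cs <- bc2[2]
      prof <- radial_mean_profile(frm$counts, frm$mask, cf, cs)
      radii <- detect_profile_peaks(prof$radius, prof$intensity,
                                    support = prof$n)
      radii <- radii[radii > 5]
      if (length(radii) < 2) stop("no rings detected after centre refinement")
    }
  }
  # A tilted detector biases the sharpness centre (ring ellipse centres
  # drift outward with radius, and off-centre profiles split rings into
  # twin peaks). The centre of an ellipse fitted to the innermost ring is
  # within a few pixels of the true beam centre: lock on with a generous
  # window, re-profile, and repeat once with the cleaner peak list.
  for (pass in 1:2) {
    r1 <- min(radii[radii > 20], radii)
    gap <- if (length(radii) > 1) min(abs(radii[radii != r1] - r1)) else Inf
    hw <- max(6, min(40, r1 / 6, 0.45 * gap))
    ps <- tryCatch(extract_ring_points(frm, conic(cf, cs, r1, r1, 0),
                                       n_profiles = 128, half_width = hw),
                   error = function(e) NULL)
    if (is.null(ps) || nrow(ps) < 12) break
    el <- tryCatch(fit_ellipse(cbind(ps$fast, ps$slow), ps$weight),
                   error = function(e) NULL)
    if (is.null(el) || abs(el$centre_fast - cf) >= r1 ||
        abs(el$centre_slow - cs) >= r1) break
    moved <- max(abs(el$centre_fast - cf), abs(el$centre_slow - cs))
    cf <- el$centre_fast; cs <- el$centre_slow
    prof <- radial_mean_profile(frm$counts, frm$mask, cf, cs)
    radii <- detect_profile_peaks(prof$radius, prof$intensity,
                                  support = prof$n)
    radii <- radii[radii > 5]
    if (length(radii) < 2) stop("no rings detected after centre refinement")
    if (moved < 1) break
  }
  px <- (detector$pixel_size_fast + detector$pixel_size_slow) / 2
  r_mm <- sort(radii) * px
  best <- match_rings_to_d(r_mm, cal$d_spacings, wavelength, px,
                           max_anchor = max_offset + 1L)
  if (is.null(best)) {
    stop("no consistent assignment of detected rings to calibrant d-spacings")
  }
  keep <- which(best$assignment > 0)
  ringi <- best$assignment[keep]
  dd <- cal$d_spacings[ringi]
  tt <- rad2deg(2 * asin(best$lam / (2 * dd)))
  geom <- diffraction_geometry(distance = best$D, beam_centre_fast = cf,
                               beam_centre_slow = cs, tilt_pitch = 0,
                               tilt_yaw = 0, wavelength = best$lam,
                               detector = detector)
  list(geometry = geom,
       rings = tibble::tibble(ring = ringi, d = dd,
                              radius_px = sort(radii)[keep],
                              two_theta = tt),
       profile = prof)
}
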