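test_that("threshold_mask flags exactly the out-of-range pixels", {
  frm <- random_frame(seed = 8)
  within <- threshold_mask(frm, -1, 1e9)
  expect_identical(within$mask, frm$mask)
  one <- frm
  one$counts[17, 23] <- 1e7
  m1 <- threshold_mask(one, -1, 1e6)
  expect_identical(which(m1$mask), which(one$counts > 1e6))
  expect_equal(sum(m1$mask), 1)
  # enumeration oracle on a random frame
  m2 <- threshold_mask(frm, 70, 90)
  expect_identical(m2$mask, frm$counts < 70 | frm$counts > 90)
  expect_identical(m2$counts, frm$counts)        # counts untouched
  expect_error(threshold_mask(frame(matrix(5, 16, 16)), 10, 20), "all pixels")
})

test_that("estimate_errors implements gain-scaled Poisson with floor", {
  frm <- frame(matrix(c(100, 0, 200, 50), 2, 2))
  e1 <- estimate_errors(frm, gain = 1)
  expect_equal(e1$errors[1, 1], 10)
  expect_equal(e1$errors[2, 1], 1)               # floor at one photon
  e2 <- estimate_errors(frm, gain = 2)
  expect_equal(e2$errors[1, 2], 2 * sqrt(100))   # 200 counts, gain 2 -> 20
  neg <- frame(matrix(-5, 16, 16))
  expect_error(estimate_errors(neg), "negative")
})

test_that("solid-angle correction is 1/cos^3(2 theta) untilted and 8 at
           60 degrees", {
  det <- detector_spec(64, 64, 0.5)
  g <- diffraction_geometry(10, 31, 31, 0, 0, wavelength = 1,
                            detector = det)   # beam centre on a pixel
  f <- diffractr:::solid_angle_factor(g)
  tt <- two_theta_map(g)
  expect_equal(f, 1 / cos(d2r(tt))^3, tolerance = 1e-12)
  # beam-centre factor exactly 1, monotone growth with radius along a row
  expect_equal(f[32, 32], 1, tolerance = 1e-12)
  expect_true(all(diff(f[32, 32:64]) > 0))
  # a pixel placed at exactly 2 theta = 60 deg: fast index 26 at
  # D = 26 / tan(60 deg) with 1 mm pixels
  det1 <- detector_spec(64, 64, 1)
  g60 <- diffraction_geometry(26 / tan(d2r(60)), 0, 31, 0, 0,
                              wavelength = 1, detector = det1)
  cor <- correct_solid_angle(frame(matrix(1, 64, 64)), g60)
  expect_equal(cor$counts[32, 27], 8, tolerance = 1e-12)
})

test_that("polarization correction follows the Kahn factor", {
  g <- untilted_geom(64, px = 0.5, distance = 10)
  tt <- d2r(two_theta_map(g)); ch <- d2r(chi_map(g))
  frm <- frame(matrix(1, 64, 64))
  # unpolarized beam: P = (1 + cos^2)/2, equal to 1 at 2 theta = 0
  c0 <- correct_polarization(frm, g, 0)
  expect_equal(c0$counts, 1 / (0.5 * (1 + cos(tt)^2)), tolerance = 1e-12)
  # towards 2 theta = 90 the unpolarized factor approaches 1/2 (counts
  # doubled); a flat detector reaches ~89 deg at distance 1 px
  det <- detector_spec(64, 64, 1)
  g90 <- diffraction_geometry(1, 0, 31, 0, 0, wavelength = 1,
                              detector = det)
  tt90 <- two_theta_map(g90)
  j <- which.max(tt90[32, ])
  expect_gt(tt90[32, j], 89)
  c90 <- correct_polarization(frame(matrix(1, 64, 64)), g90, 0)
  expect_equal(c90$counts[32, j], 2, tolerance = 1e-3)
  # xi = 1, chi = 0: P = cos^2(2 theta) -> vanishes at 90 deg, so the
  # near-90 pixel is masked instead of divided
  c1 <- correct_polarization(frame(matrix(1, 64, 64)), g90, 1,
                             eps = 1e-3)
  expect_true(c1$mask[32, j])
  expect_false(c1$mask[32, 2])
  # full xi = 0.95 field matches the formula
  cx <- correct_polarization(frm, g, 0.95)
  P <- 0.5 * (1 + cos(tt)^2 - 0.95 * cos(2 * ch) * sin(tt)^2)
  expect_equal(cx$counts[!cx$mask], (1 / P)[!cx$mask], tolerance = 1e-12)
})

test_that("corrections commute (elementwise multiplications)", {
  g <- untilted_geom(64, px = 0.5, distance = 12)
  frm <- estimate_errors(random_frame(seed = 2))
  a <- correct_polarization(correct_solid_angle(frm, g), g, 0.5)
  b <- correct_solid_angle(correct_polarization(frm, g, 0.5), g)
  expect_equal(a$counts, b$counts, tolerance = 1e-12)
  expect_equal(a$errors, b$errors, tolerance = 1e-12)
})

test_that("divide handles scalars, metadata keys and reference frames", {
  frm <- frame(matrix(10, 16, 16), errors = matrix(1, 16, 16),
               metadata = list(monitor = 2))
  expect_identical(divide_frame(frm, 1)$counts, frm$counts)
  half <- divide_frame(frm, "monitor")
  expect_true(all(half$counts == 5) && all(half$errors == 0.5))
  expect_error(divide_frame(frm, "nope"), "missing")
  expect_error(divide_frame(frm, 0), "nonzero")
  ref <- frame(matrix(2, 16, 16), errors = matrix(0.2, 16, 16))
  q <- divide_frame(frm, ref)
  expect_true(all(abs(q$counts - 5) < 1e-12))
  expect_equal(q$errors[1, 1], 5 * sqrt(0.01 + 0.01), tolerance = 1e-12)
})

test_that("azimuthal integration (no splitting) is bitwise equal to a
           brute-force per-pixel histogram", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- estimate_errors(random_frame(seed = 3))
  frm$mask[5:10, 40:45] <- TRUE
  n_bins <- 50
  qm <- q_map(g)
  rng <- range(qm[!frm$mask])
  p <- integrate_azimuthal(frm, g, n_bins = n_bins, radial_range = rng)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  sel <- which(!frm$mask)
  bins <- findInterval(qm[sel], edges, rightmost.closed = TRUE)
  I <- E <- W <- rep(NA_real_, n_bins); V <- logical(n_bins)
  for (b in seq_len(n_bins)) {
    ii <- sel[bins == b]
    if (!length(ii)) { W[b] <- 0; next }
    w <- 0; cs <- 0; e2 <- 0
    for (i in ii) {
      w <- w + 1; cs <- cs + frm$counts[i]; e2 <- e2 + frm$errors[i]^2
    }
    W[b] <- w; I[b] <- cs / w; E[b] <- sqrt(e2) / w; V[b] <- TRUE
  }
  expect_identical(p$intensity, I)
  expect_identical(p$error, E)
  expect_identical(p$weight, W)
  expect_identical(p$valid, V)
})

test_that("flat field integrates to a flat profile equal to the constant", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- frame(matrix(42, 64, 64))
  p <- integrate_azimuthal(frm, g, n_bins = 30)
  expect_true(all(abs(p$intensity[p$valid] - 42) < 1e-12))
  pb <- integrate_azimuthal(frm, g, n_bins = 30, splitting = "bbox")
  expect_true(all(abs(pb$intensity[pb$valid] - 42) < 1e-12))
})

test_that("bbox splitting conserves total weight to 1e-9 relative", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- random_frame(seed = 4)
  frm$mask[1:4, 1:64] <- TRUE
  p <- integrate_azimuthal(frm, g, n_bins = 37, splitting = "bbox")
  n_unmasked <- sum(!frm$mask)
  expect_lt(abs(sum(p$weight) - n_unmasked) / n_unmasked, 1e-9)
  ck <- cake_remap(frm, g, n_radial = 23, n_azimuthal = 16,
                   splitting = "bbox")
  expect_lt(abs(sum(ck$weights) - n_unmasked) / n_unmasked, 1e-9)
})

test_that("synthetic ring integrates to a peak within half a bin of 2 pi/d", {
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(cal$d_spacings[2]), f)
  one <- load_calibrant(f)
  g <- diffraction_geometry(55, 127.5, 127.5, 0.5, -0.4, energy_keV = 25.5,
                            detector = det)
  frm <- render_calibration_image(g, one, ring_amplitudes = 1000,
                                  ring_width_q = 0.02, background = 5,
                                  noise = "none")
  p <- integrate_azimuthal(frm, g, n_bins = 400)
  q_true <- 2 * pi / one$d_spacings[1]
  bin_w <- diff(p$radial[1:2])
  expect_lt(abs(p$radial[which.max(p$intensity)] - q_true), bin_w / 2 + 1e-12)
})

test_that("integration errors behave as sigma/sqrt(N) for equal pixels", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- frame(matrix(5, 64, 64), errors = matrix(2, 64, 64))
  p <- integrate_azimuthal(frm, g, n_bins = 4)
  expect_equal(p$error[p$valid], 2 / sqrt(p$weight[p$valid]),
               tolerance = 1e-12)
})

test_that("results are invariant to the stored values of masked pixels", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- estimate_errors(random_frame(seed = 5))
  frm$mask[20:30, 20:30] <- TRUE
  fuzz <- frm
  fuzz$counts[fuzz$mask] <- withr::with_seed(99, runif(sum(fuzz$mask), -1e9, 1e9))
  for (sp in c("none", "bbox")) {
    a <- integrate_azimuthal(frm, g, n_bins = 40, splitting = sp)
    b <- integrate_azimuthal(fuzz, g, n_bins = 40, splitting = sp)
    expect_identical(a$intensity, b$intensity)
  }
  ca <- cake_remap(frm, g, n_radial = 20, n_azimuthal = 12)
  cb <- cake_remap(fuzz, g, n_radial = 20, n_azimuthal = 12)
  expect_identical(ca$intensity, cb$intensity)
})

test_that("cake collapse reproduces direct integration; one azimuth row is
           the integration itself", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- estimate_errors(random_frame(seed = 6))
  qm <- q_map(g)
  rng <- range(qm)
  for (sp in c("none", "bbox")) {
    p <- integrate_azimuthal(frm, g, n_bins = 40, radial_range = rng,
                             splitting = sp)
    ck <- cake_remap(frm, g, n_radial = 40, n_azimuthal = 24,
                     radial_range = rng, splitting = sp)
    pc <- collapse_cake(ck)
    ok <- p$valid & pc$valid
    expect_lt(max(abs(pc$intensity[ok] - p$intensity[ok]) /
                  pmax(abs(p$intensity[ok]), 1e-12)), 1e-9)
  }
  ck1 <- cake_remap(frm, g, n_radial = 40, n_azimuthal = 1,
                    radial_range = rng)
  p1 <- integrate_azimuthal(frm, g, n_bins = 40, radial_range = rng)
  expect_equal(as.vector(ck1$intensity[1, ]), p1$intensity)
})

test_that("an untilted ideal ring forms a constant-radius ridge in the cake", {
  det <- detector_spec(128, 128, 0.4)
  cal <- load_calibrant("CeO2_SRM674b")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(cal$d_spacings[1]), f)
  one <- load_calibrant(f)
  g <- diffraction_geometry(28, 63.5, 63.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  frm <- render_calibration_image(g, one, ring_amplitudes = 1000,
                                  ring_width_q = 0.03, background = 1,
                                  noise = "none")
  ck <- cake_remap(frm, g, n_radial = 60, n_azimuthal = 16)
  ridge <- apply(ck$intensity, 1, function(row)
    if (all(is.na(row))) NA_integer_ else which.max(row))
  ridge <- ridge[!is.na(ridge)]
  expect_lte(diff(range(ridge)), 1)
})

test_that("azimuth ranges crossing the seam are handled by rotation", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- random_frame(seed = 7)
  ck <- cake_remap(frm, g, n_radial = 20, n_azimuthal = 8,
                   azimuth_range = c(150, -150))
  expect_equal(dim(ck$intensity), c(8, 20))
  cm <- chi_map(g)
  sel <- cm >= 150 | cm <= -150
  expect_equal(sum(ck$weights), sum(sel & is.finite(q_map(g)) &
                                    q_map(g) >= min(ck$radial_centres) - 1))
})

test_that("dynamic background subtraction preserves peak area and is the
           identity at zero iterations", {
  x <- seq(0, 10, length.out = 400)
  sig <- 0.15
  peak <- 800 * exp(-(x - 4)^2 / (2 * sig^2))
  bgr <- 200 + 30 * x                       # linear baseline
  prof <- diffractr:::radial_profile(x, bgr + peak, rep(5, 400), rep(1, 400),
                                     rep(TRUE, 400))
  out0 <- subtract_radial_background(prof, iterations = 0)
  expect_identical(out0$intensity, prof$intensity)
  # window chosen wider than the peak (the one tunable that matters here)
  out <- subtract_radial_background(prof, iterations = 30, clip_factor = 2,
                                    window = 61)
  # peak-free region is flattened to ~0
  flat <- abs(out$intensity[x > 6])
  expect_lt(stats::median(flat), 5)
  # peak area preserved within 2%
  sel <- x > 3 & x < 5
  area_true <- sum(peak[sel]) * diff(x[1:2])
  area_est <- sum(out$intensity[sel]) * diff(x[1:2])
  expect_lt(abs(area_est - area_true) / area_true, 0.02)
  # smooth (curved) peak-free profile -> residual ~ 0 everywhere
  smoothp <- diffractr:::radial_profile(x, 200 + 30 * x - 1.5 * x^2,
                                        rep(5, 400), rep(1, 400),
                                        rep(TRUE, 400))
  outs <- subtract_radial_background(smoothp, iterations = 20)
  expect_lt(max(abs(outs$intensity[20:380])), 3)
})

test_that("frame-level background subtraction leaves the ring, removes the
           radial background", {
  det <- detector_spec(128, 128, 0.4)
  cal <- load_calibrant("CeO2_SRM674b")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(cal$d_spacings[1]), f)
  one <- load_calibrant(f)
  g <- diffraction_geometry(28, 63.5, 63.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  frm <- render_calibration_image(g, one, ring_amplitudes = 500,
                                  ring_width_q = 0.03,
                                  background = c(100, 20), noise = "none")
  sub <- subtract_radial_background(frm, g, iterations = 30, n_bins = 128)
  qm <- q_map(g)
  q1 <- 2 * pi / one$d_spacings[1]
  off_ring <- abs(qm - q1) > 0.3
  expect_lt(stats::median(abs(sub$counts[off_ring])), 5)
  expect_gt(max(sub$counts[!off_ring]), 300)
})
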