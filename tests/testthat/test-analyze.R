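gauss_profile <- function(centre = 5, fwhm = 0.5, amp = 1000,
                          base = c(100, 5), n = 300, noise = FALSE,
                          seed = NULL) {
  x <- seq(1, 10, length.out = n)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  y <- base[1] + base[2] * x + amp * exp(-(x - centre)^2 / (2 * sig^2))
  make <- function() {
    if (noise) {
      yy <- rpois(n, y)
      tibble::tibble(radial = x, intensity = yy, error = sqrt(pmax(yy, 1)))
    } else tibble::tibble(radial = x, intensity = y)
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

test_that("fit_peak recovers a noiseless Gaussian exactly", {
  pr <- fit_peak(gauss_profile(), c(3.5, 6.5))
  expect_true(pr$success)
  expect_equal(pr$centre, 5, tolerance = 1e-6)
  expect_equal(pr$fwhm, 0.5, tolerance = 1e-6)
  sig <- 0.5 / (2 * sqrt(2 * log(2)))
  expect_equal(pr$area, 1000 * sig * sqrt(2 * pi), tolerance = 1e-5)
  # FWHM/sigma relation is the exact closed form
  expect_equal(2 * sqrt(2 * log(2)) * sig, pr$fwhm, tolerance = 1e-12)
})

test_that("pseudo-Voigt shape also fits (pure Gaussian limit)", {
  pr <- fit_peak(gauss_profile(), c(3.5, 6.5), shape = "pseudo_voigt")
  expect_true(pr$success)
  expect_equal(pr$centre, 5, tolerance = 1e-4)
  expect_equal(pr$fwhm, 0.5, tolerance = 0.02)
})

test_that("flat profiles fail flagged, windows outside the axis error", {
  x <- seq(1, 10, length.out = 100)
  flat <- tibble::tibble(radial = x, intensity = rep(7, 100))
  pr <- fit_peak(flat, c(3, 7))
  expect_false(pr$success)
  expect_error(fit_peak(flat, c(20, 30)), "outside")
  few <- tibble::tibble(radial = x[1:5], intensity = rep(1, 5))
  expect_false(fit_peak(few, c(0, 20))$success)
})

test_that("reported centre uncertainties give ~3 sigma coverage", {
  hits <- withr::with_seed(31, {
    vapply(1:100, function(i) {
      pr <- fit_peak(gauss_profile(noise = TRUE), c(3.5, 6.5))
      u <- pr$uncertainties[["centre"]]
      isTRUE(pr$success && is.finite(u) && abs(pr$centre - 5) <= 3 * u)
    }, TRUE)
  })
  expect_gte(sum(hits), 99)
})

test_that("track_peak finds a step change and tolerates bad frames", {
  ser <- render_peak_shift_series(
    150, c(rep(5, 74), rep(5.4, 76)), rep(0.5, 150),
    noise = "poisson", seed = 9)
  tr <- track_peak(ser, c(3.5, 6.8))
  expect_equal(nrow(tr), 150)
  expect_true(all(tr$success))
  expect_equal(which.max(abs(diff(tr$centre))) + 1L, 75L)
  expect_lt(max(abs(tr$fwhm - 0.5)), 0.05)
  # constant series -> constant trajectory
  cons <- render_peak_shift_series(5, rep(5, 5), rep(0.5, 5), noise = "none")
  trc <- track_peak(cons, c(3.5, 6.5))
  expect_lt(diff(range(trc$centre)), 1e-8)
  # one corrupted frame is flagged, neighbours unaffected
  bad <- ser
  bad$data[40, ] <- 0
  trb <- track_peak(bad, c(3.5, 6.8))
  expect_false(trb$success[40])
  expect_true(trb$success[39] && trb$success[41])
  expect_lt(abs(trb$centre[41] - 5), 0.02)
})

test_that("azimuthal_profile averages a q band of the cake", {
  g <- untilted_geom(64, px = 0.5, distance = 20)
  frm <- frame(matrix(13, 64, 64))
  ck <- cake_remap(frm, g, n_radial = 30, n_azimuthal = 24)
  ap <- azimuthal_profile(ck, range(ck$radial_centres))
  expect_true(all(abs(ap$intensity[ap$valid] - 13) < 1e-12))
  # one-bin band equals that cake column
  band <- ck$radial_centres[15] + c(-1e-9, 1e-9)
  ap1 <- azimuthal_profile(ck, band)
  ord <- order(ck$azimuth_centres)
  expect_equal(ap1$intensity, ck$intensity[ord, 15])
  expect_error(azimuthal_profile(ck, c(1e6, 2e6)), "overlap")
})

test_that("orientation metrics match the analytic cos^2 results", {
  chi <- seq(-179.75, 179.75, by = 0.5)
  I <- 1 + cos(d2r(chi - 40))^2
  om <- orientation_metrics(tibble::tibble(chi = chi, intensity = I),
                            floor_percentile = 0)
  # degree = (integral cos^2) / (integral 1 + cos^2) = (1/2)/(3/2) = 1/3
  expect_equal(om$degree, 1 / 3, tolerance = 1e-3)
  expect_equal(om$direction, 40, tolerance = 1e-6)
  # zero baseline: degree 1, direction 0
  om2 <- orientation_metrics(
    tibble::tibble(chi = chi, intensity = cos(d2r(chi))^2),
    floor_percentile = 0)
  expect_equal(om2$degree, 1, tolerance = 1e-3)
  expect_equal(om2$direction, 0, tolerance = 1e-6)
  # flat: degree 0, direction flagged invalid
  om3 <- orientation_metrics(tibble::tibble(chi = chi,
                                            intensity = rep(2, length(chi))))
  expect_equal(om3$degree, 0)
  expect_false(om3$direction_valid)
  expect_true(is.na(om3$direction))
})

test_that("degree is scale invariant; direction is rotation equivariant
           modulo 180", {
  chi <- seq(-177.5, 180, by = 5)
  I <- 2 + 3 * cos(d2r(chi - 25))^2
  base <- orientation_metrics(tibble::tibble(chi = chi, intensity = I))
  scaled <- orientation_metrics(tibble::tibble(chi = chi, intensity = 7 * I))
  expect_equal(base$degree, scaled$degree, tolerance = 1e-12)
  for (rot in c(30, 90, 170)) {
    Ir <- 2 + 3 * cos(d2r(chi - 25 - rot))^2
    omr <- orientation_metrics(tibble::tibble(chi = chi, intensity = Ir))
    dd <- (omr$direction - base$direction - rot) %% 180
    expect_lt(min(dd, 180 - dd), 1e-6)
  }
  expect_error(orientation_metrics(tibble::tibble(chi = chi[1:5],
                                                  intensity = rep(1, 5))),
               "8 valid")
  expect_error(orientation_metrics(tibble::tibble(chi = chi,
                                                  intensity = rep(0, length(chi)))))
})

test_that("orientation_map recovers a direction field on a grid scan", {
  g <- untilted_geom(96, px = 0.5, distance = 50)
  dirs <- matrix(seq(-60, 75, length.out = 12), 3, 4)
  scan <- render_oriented_grid_scan(c(3, 4), g, iso_amplitude = 50,
                                    aniso_amplitude = 300,
                                    direction_field = dirs,
                                    q_band = c(1.2, 2.2), noise = "none")
  omap <- orientation_map(scan, g, c(1.2, 2.2))
  expect_equal(dim(omap$degree), c(3, 4))
  expect_equal(dim(omap$direction), c(3, 4))
  expect_equal(omap$axes[[1]]$name, "stage_y")
  expect_lt(max(abs(omap$direction - dirs)), 2)
  # isotropic scan: degree ~ 0 under Poisson noise
  iso <- render_oriented_grid_scan(c(2, 2), g, iso_amplitude = 200,
                                   aniso_amplitude = 0,
                                   q_band = c(1.2, 2.2),
                                   noise = "poisson", seed = 12)
  miso <- orientation_map(iso, g, c(1.2, 2.2))
  expect_lt(max(miso$degree), 0.05)
})
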