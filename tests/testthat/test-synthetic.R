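test_that("zero-amplitude render is the constant background", {
  sc <- calib_scene(n = 64)
  frm <- render_calibration_image(sc$geometry, sc$calibrant,
                                  ring_amplitudes = 0, background = 100,
                                  noise = "none")
  expect_true(all(frm$counts[!frm$mask] == 100))
})

test_that("single-ring argmax sits at D tan(2 theta) on any radial ray", {
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(60, 127.5, 127.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  # keep only the first ring by masking the others via a custom line list
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(cal$d_spacings[1]), f)
  one <- load_calibrant(f)
  frm <- render_calibration_image(g, one, ring_amplitudes = 1000,
                                  ring_width_q = 0.02, background = 10,
                                  noise = "none")
  r_true <- 60 * tan(d2r(ring_positions(one, g$wavelength)$two_theta[1])) / 0.2
  for (ang in c(0, 45, 133)) {
    rr <- seq(5, 120, by = 1)
    fast <- round(127.5 + rr * cos(d2r(ang)))
    slow <- round(127.5 + rr * sin(d2r(ang)))
    prof <- frm$counts[cbind(slow + 1, fast + 1)]
    expect_lt(abs(rr[which.max(prof)] - r_true), 1.5)
  }
})

test_that("generators are bit-reproducible under a seed", {
  sc <- calib_scene(n = 64)
  a <- render_calibration_image(sc$geometry, sc$calibrant, noise = "poisson",
                                seed = 5)
  b <- render_calibration_image(sc$geometry, sc$calibrant, noise = "poisson",
                                seed = 5)
  c_ <- render_calibration_image(sc$geometry, sc$calibrant, noise = "poisson",
                                 seed = 6)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c_$counts))
  s1 <- render_peak_shift_series(5, rep(5, 5), rep(0.5, 5),
                                 noise = "poisson", seed = 2)
  s2 <- render_peak_shift_series(5, rep(5, 5), rep(0.5, 5),
                                 noise = "poisson", seed = 2)
  expect_identical(s1$data, s2$data)
  g1 <- render_oriented_grid_scan(c(2, 2), untilted_geom(32),
                                  noise = "poisson", seed = 3)
  g2 <- render_oriented_grid_scan(c(2, 2), untilted_geom(32),
                                  noise = "poisson", seed = 3)
  expect_identical(g1$data, g2$data)
})

test_that("masked pixels carry the saturation sentinel", {
  det <- detector_spec(64, 64, 0.5,
                       static_mask = {
                         m <- matrix(FALSE, 64, 64); m[10:20, 30] <- TRUE; m
                       })
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(15, 31.5, 31.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  frm <- render_calibration_image(g, cal, noise = "none")
  expect_true(all(frm$counts[det$static_mask] == det$saturation))
  expect_true(all(frm$mask[det$static_mask]))
})

test_that("a ring-free geometry warns and returns background only", {
  det <- detector_spec(64, 64, 0.01)      # tiny detector, rings off it
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(5000, 31.5, 31.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  expect_warning(frm <- render_calibration_image(g, cal, background = 7,
                                                 noise = "none"),
                 "no calibrant ring")
  expect_true(all(frm$counts[!frm$mask] == 7))
})

test_that("distance series: zero increment reproduces the single image and
           fitted radius grows linearly with slope tan(2 theta)", {
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(50, 127.5, 127.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  single <- render_calibration_image(g, cal, noise = "none")
  series0 <- render_distance_series(g, cal, 0, noise = "none")
  expect_identical(series0[[1]]$counts, single$counts)
  inc <- c(0, 5, 10, 15, 20)
  f1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(cal$d_spacings[1]), f1)   # isolate ring 1
  one <- load_calibrant(f1)
  # ring width ~1 px at this dispersion (sub-pixel rings alias)
  ser <- render_distance_series(g, one, inc, ring_amplitudes = 1000,
                                ring_width_q = 0.05, background = 10,
                                noise = "none")
  expect_length(ser, 5)
  # per frame, radius of ring 1 via an intensity-weighted centroid about
  # the profile maximum (the argmax of a piecewise-linear interpolant
  # snaps to grid nodes)
  r_of <- function(frm) {
    rr <- seq(2, 126, by = 0.1)
    prof <- diffractr:::bilinear_sample(frm$counts, frm$mask,
                                        127.5 + rr, rep(127.5, length(rr)))
    pk <- rr[which.max(prof)]
    sel <- abs(rr - pk) < 4
    wgt <- pmax(prof[sel] - 10, 0)       # background level is 10
    sum(rr[sel] * wgt) / sum(wgt)
  }
  radii <- vapply(ser, r_of, 0) * 0.2
  sl <- stats::coef(stats::lm(radii ~ inc))[2]
  tt1 <- d2r(ring_positions(cal, g$wavelength)$two_theta[1])
  expect_equal(unname(sl), tan(tt1), tolerance = 0.01)
  expect_error(render_distance_series(g, cal, c(0, -60)), "<= 0")
})

test_that("peak-shift series obeys the FWHM/sigma closed form", {
  ax <- seq(1, 10, length.out = 2001)
  ser <- render_peak_shift_series(3, rep(5, 3), rep(0.8, 3), axis = ax,
                                  amplitude = 1000, background = c(0, 0),
                                  noise = "none")
  y <- ser$data[1, ]
  expect_identical(ser$data[1, ], ser$data[3, ])   # constant trajectory
  half <- max(y) / 2
  above <- range(ax[y >= half])
  expect_equal(diff(above), 0.8, tolerance = 0.02)
  sig <- 0.8 / (2 * sqrt(2 * log(2)))
  expect_equal(y[which.min(abs(ax - 5 - sig))] / max(y), exp(-0.5),
               tolerance = 0.01)
})

test_that("oriented grid scan has rank 4, stage axes and stated truth", {
  g <- untilted_geom(48)
  scan <- render_oriented_grid_scan(c(3, 4), g, direction_field = 25,
                                    q_band = c(0.8, 1.8), noise = "none")
  expect_equal(length(dim(scan$data)), 4)
  expect_equal(scan_rank(scan), 2)
  expect_equal(scan$axes[[1]]$name, "stage_y")
  expect_equal(scan$axes[[2]]$name, "stage_x")
  expect_equal(dim(scan$metadata$truth$direction), c(3, 4))
  # isotropic everywhere -> azimuthally flat inside the band
  iso <- render_oriented_grid_scan(c(1, 1), g, aniso_amplitude = 0,
                                   q_band = c(0.8, 1.8), noise = "none")
  img <- iso$data[1, 1, , ]
  qm <- q_map(g)
  inband <- img[qm >= 0.8 & qm <= 1.8]
  expect_lt(diff(range(inband)), 1e-9)
})

test_that("inverse corrections cancel against the reduce-module factors", {
  det <- detector_spec(128, 128, 0.4)
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(25, 63.5, 63.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  plain <- render_calibration_image(g, cal, background = 50, noise = "none")
  inv <- render_calibration_image(g, cal, background = 50, noise = "none",
                                  apply_inverse_corrections = TRUE,
                                  polarization_fraction = 0.5)
  rec <- correct_polarization(correct_solid_angle(inv, g), g, 0.5)
  expect_equal(rec$counts, plain$counts, tolerance = 1e-12)
})
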