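# exact ring point sets straight from the forward model (no image in
# between): the cleanest oracle for the refinement contract
exact_ring_points <- function(geom, d, n = 64, jitter = 0, seed = NULL) {
  con <- predict_ring(geom, d)
  make <- function() {
    pts <- conic_points(con, seq(0, 2 * pi, length.out = n + 1)[-(n + 1)])
    if (jitter > 0) {
      pts$fast <- pts$fast + rnorm(n, 0, jitter)
      pts$slow <- pts$slow + rnorm(n, 0, jitter)
    }
    out <- tibble::tibble(fast = pts$fast, slow = pts$slow,
                          weight = rep(if (jitter > 0) 1 / jitter^2 else 1e6, n))
    attr(out, "d_spacing") <- d
    out
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

test_geom <- function() {
  det <- detector_spec(512, 512, 0.2)
  diffraction_geometry(180, 250, 270, 1.5, -0.9, energy_keV = 25.5,
                       detector = det)
}

test_that("refinement at the truth with noiseless points is a no-op", {
  g <- test_geom()
  dlist <- load_calibrant("CeO2_SRM674b")$d_spacings[1:5]
  sets <- lapply(dlist, function(d) exact_ring_points(g, d))
  res <- refine_geometry(sets, g, fixed = "wavelength")
  expect_lt(res$residual_rms_q, 1e-10)
  expect_equal(res$geometry$distance, g$distance, tolerance = 1e-10)
  expect_equal(res$n_rings, 5)
})

test_that("refinement recovers a perturbed geometry from noiseless points", {
  g <- test_geom()
  dlist <- load_calibrant("CeO2_SRM674b")$d_spacings[1:5]
  sets <- lapply(dlist, function(d) exact_ring_points(g, d))
  start <- g
  start$distance <- g$distance * 1.05
  start$tilt_pitch <- g$tilt_pitch + 2
  start$beam_centre_fast <- g$beam_centre_fast + 3
  start$beam_centre_slow <- g$beam_centre_slow - 3
  res <- refine_geometry(sets, start, fixed = "wavelength")
  expect_lt(abs(res$geometry$distance - g$distance) / g$distance, 1e-4)
  expect_lt(abs(res$geometry$beam_centre_fast - g$beam_centre_fast), 1e-3)
  expect_lt(abs(res$geometry$tilt_pitch - g$tilt_pitch), 1e-3)
  expect_lt(abs(res$geometry$tilt_yaw - g$tilt_yaw), 1e-3)
})

test_that("a single ring cannot separate distance and wavelength", {
  det <- detector_spec(512, 512, 0.2)
  g <- diffraction_geometry(180, 250, 270, 0, 0, energy_keV = 25.5,
                            detector = det)   # untilted: exact degeneracy
  d1 <- load_calibrant("CeO2_SRM674b")$d_spacings[1]
  sets <- list(exact_ring_points(g, d1))
  expect_error(
    refine_geometry(sets, g,
                    fixed = c("beam_centre_fast", "beam_centre_slow",
                              "tilt_pitch", "tilt_yaw")),
    "singular|cannot be separated")
})

test_that("tidy/glance expose the six-parameter partition", {
  g <- test_geom()
  dlist <- load_calibrant("CeO2_SRM674b")$d_spacings[1:4]
  sets <- lapply(dlist, function(d) exact_ring_points(g, d, jitter = 0.05,
                                                      seed = 3))
  res <- refine_geometry(sets, g, fixed = "wavelength",
                         calibrant_name = "CeO2_SRM674b")
  td <- tidy(res)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$fixed), 1)
  expect_equal(sum(!td$fixed) + sum(td$fixed), 6)   # exactly 6 partitioned
  expect_true(all(td$std_error[!td$fixed] >= 0))
  gl <- glance(res)
  expect_equal(gl$n_free, 5L)
  expect_equal(gl$calibrant, "CeO2_SRM674b")
})

test_that("uncertainties shrink like 1/sqrt(n_points)", {
  g <- test_geom()
  dlist <- load_calibrant("CeO2_SRM674b")$d_spacings[1:5]
  run <- function(n) {
    sets <- lapply(seq_along(dlist), function(i)
      exact_ring_points(g, dlist[i], n = n, jitter = 0.2, seed = 40 + i + n))
    refine_geometry(sets, g, fixed = "wavelength")
  }
  u1 <- run(32)$uncertainties
  u2 <- run(128)$uncertainties
  ratio <- u1 / u2           # expect ~ sqrt(128/32) = 2
  expect_true(all(ratio > 1.4 & ratio < 2.9))
})

test_that("auto single-image calibration meets its accuracy contract", {
  sc <- calib_scene(n = 512, distance = 180, cf = 250, cs = 270,
                    pitch = 1.2, yaw = -0.8, noise = "poisson", seed = 42)
  res <- calibrate_auto_single(sc$frame, sc$calibrant, sc$detector,
                               wavelength = sc$geometry$wavelength)
  expect_equal(res$routine, "auto_single")
  expect_lt(abs(res$geometry$distance - 180) / 180, 0.001)
  expect_lt(abs(res$geometry$beam_centre_fast - 250), 0.2)
  expect_lt(abs(res$geometry$beam_centre_slow - 270), 0.2)
  expect_lt(abs(res$geometry$tilt_pitch - 1.2), 0.05)
  expect_lt(abs(res$geometry$tilt_yaw + 0.8), 0.05)
  expect_equal(res$fixed_parameters, "wavelength")
})

test_that("wavelength-free calibration with only low-angle rings reports
           the Bragg ambiguity", {
  # high energy, rings all below ~5 degrees
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(430, 127.5, 127.5, 0, 0, energy_keV = 80,
                            detector = det)
  frm <- render_calibration_image(g, cal, ring_amplitudes = 2000,
                                  ring_width_q = 0.02, background = 20,
                                  noise = "none")
  expect_lt(max(ring_positions(cal, g$wavelength,
                               max(two_theta_map(g)))$two_theta), 5)
  expect_error(calibrate_auto_single(frm, cal, det, wavelength = NULL),
               "ambiguity")
})

test_that("beam centre far off the detector defeats the automatic route", {
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(120, -300, 127.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  frm <- render_calibration_image(g, cal, ring_amplitudes = 2000,
                                  background = 20, noise = "none")
  expect_error(calibrate_auto_single(frm, cal, det,
                                     wavelength = g$wavelength))
})

test_that("multi-distance: 2 distances + 1 ring match the linear closed
           form and recover D0 exactly on noiseless input", {
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(cal$d_spacings[1]), f)
  one <- load_calibrant(f)
  g <- diffraction_geometry(50, 127.5, 127.5, 0, 0, energy_keV = 25.5,
                            detector = det)
  inc <- c(0, 15)
  frames <- render_distance_series(g, one, inc, ring_amplitudes = 1000,
                                   ring_width_q = 0.05, background = 10,
                                   noise = "none")
  res <- solve_multi_distance(frames, inc, one, det,
                              wavelength = g$wavelength)
  alg <- attr(res, "algebraic")
  a <- alg$semi_major_mm
  D0_closed <- (a[2, 1] * inc[1] - a[1, 1] * inc[2]) / (a[1, 1] - a[2, 1])
  expect_equal(alg$D0, D0_closed, tolerance = 1e-9)   # same linear algebra
  expect_lt(abs(alg$D0 - 50) / 50, 0.01)   # algebraic seed, pre-polish
  expect_lt(abs(res$geometry$distance - 50) / 50, 1e-3)
  expect_equal(res$routine, "auto_multi")
})

test_that("duplicate distance increments are rejected", {
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  frames <- list(frame(matrix(1, 256, 256)), frame(matrix(1, 256, 256)))
  expect_error(solve_multi_distance(frames, c(5, 5), cal, det), "distinct")
})

test_that("multi-distance and single-image calibrations agree within
           combined uncertainties on the same series", {
  det <- detector_spec(256, 256, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  g <- diffraction_geometry(52, 130, 125, 0.4, 0.6, energy_keV = 25.5,
                            detector = det)
  inc <- c(0, 8, 16)
  frames <- render_distance_series(g, cal, inc, ring_amplitudes = 3000,
                                   ring_width_q = 0.02, background = 30,
                                   noise = "poisson", seed = 17)
  multi <- solve_multi_distance(frames, inc, cal, det,
                                wavelength = g$wavelength)
  single <- calibrate_auto_single(frames[[1]], cal, det,
                                  wavelength = g$wavelength)
  # the two estimates share frame 1 (correlated), and sub-pixel extraction
  # systematics leave a small floor below the statistical errors
  for (par in c("distance", "beam_centre_fast", "beam_centre_slow")) {
    diffp <- abs(multi$geometry[[par]] - single$geometry[[par]])
    comb <- sqrt(multi$uncertainties[[par]]^2 + single$uncertainties[[par]]^2)
    expect_lt(diffp, 5 * comb + 0.02)
  }
})

test_that("manual route: exact guess converges immediately; 45-degree tilt
           with a perturbed guess recovers; a wild guess fails loudly", {
  det <- detector_spec(256, 256, 0.172)
  cal <- load_calibrant("Si_SRM640c")
  g <- diffraction_geometry(60, 128, 200, 45, 3, energy_keV = 12,
                            detector = det)
  frm <- render_calibration_image(g, cal, ring_amplitudes = 3000,
                                  ring_width_q = 0.02, background = 30,
                                  noise = "poisson", seed = 5)
  res0 <- calibrate_manual(frm, cal, g, fixed = "wavelength")
  expect_equal(res0$routine, "manual")
  expect_lt(abs(res0$geometry$distance - 60) / 60, 0.001)
  guess <- g
  guess$distance <- 60 * 1.05
  guess$tilt_pitch <- 43; guess$tilt_yaw <- 1
  guess$beam_centre_fast <- 128 - 5; guess$beam_centre_slow <- 200 + 5
  res <- calibrate_manual(frm, cal, guess, fixed = "wavelength")
  expect_lt(abs(res$geometry$distance - 60) / 60, 0.001)
  expect_lt(abs(res$geometry$tilt_pitch - 45), 0.1)
  expect_lt(abs(res$geometry$tilt_yaw - 3), 0.1)
  # a guess bad enough that the predicted arcs never cross the measured
  # ones must fail loudly with per-ring acceptance diagnostics
  wild <- g
  wild$tilt_pitch <- 5
  wild$distance <- 110
  expect_error(calibrate_manual(frm, cal, wild, fixed = "wavelength"),
               "ring-finding failed|too few|accepted")
})

test_that("calibration results round-trip through the NeXus layout", {
  g <- test_geom()
  dlist <- load_calibrant("CeO2_SRM674b")$d_spacings[1:4]
  sets <- lapply(dlist, function(d) exact_ring_points(g, d, jitter = 0.05,
                                                      seed = 9))
  res <- refine_geometry(sets, g, fixed = "wavelength", routine = "manual",
                         calibrant_name = "CeO2_SRM674b")
  path <- withr::local_tempfile(fileext = ".nxs")
  save_calibration(res, path)
  back <- load_calibration(path)
  for (nm in diffractr:::.geom_par_names) {
    expect_equal(back$geometry[[nm]], res$geometry[[nm]], tolerance = 1e-12)
  }
  expect_equal(back$uncertainties, res$uncertainties, tolerance = 1e-12)
  expect_identical(back$routine, res$routine)
  expect_identical(back$calibrant_name, "CeO2_SRM674b")
  expect_identical(back$fixed_parameters, "wavelength")
  expect_equal(back$residual_rms_q, res$residual_rms_q, tolerance = 1e-12)
})

test_that("loading a calibration without a wavelength names the field", {
  path <- withr::local_tempfile(fileext = ".nxs")
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "/entry")
  rhdf5::h5createGroup(path, "/entry/calibration")
  for (nm in c("distance", "beam_centre_fast", "beam_centre_slow",
               "tilt_pitch", "tilt_yaw")) {
    rhdf5::h5write(100, path, file.path("/entry/calibration", nm))
  }
  rhdf5::h5closeAll()
  expect_error(load_calibration(path), "wavelength")
})
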