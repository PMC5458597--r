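# Shared fixtures: small detectors/geometries and generators kept cheap so
# the default suite stays fast; the acceptance suite scales sizes up.

hc_keV_A <- 12.398419843320026
d2r <- function(x) x * pi / 180

small_detector <- function(n = 64, px = 0.5) detector_spec(n, n, px)

untilted_geom <- function(n = 64, px = 0.5, distance = 30, wavelength = 1.0) {
  detn <- small_detector(n, px)
  diffraction_geometry(distance, (n - 1) / 2, (n - 1) / 2, 0, 0,
                       wavelength = wavelength, detector = detn)
}

# standard mid-size calibration scene used across ringfind/calibrate tests
calib_scene <- function(n = 512, distance = 180, cf = 250, cs = 270,
                        pitch = 1.2, yaw = -0.8, energy = 25.5,
                        noise = "none", seed = 42, ...) {
  detn <- detector_spec(n, n, 0.2)
  cal <- load_calibrant("CeO2_SRM674b")
  geom <- diffraction_geometry(distance, cf, cs, pitch, yaw,
                               energy_keV = energy, detector = detn)
  frm <- render_calibration_image(geom, cal, ring_amplitudes = 2000,
                                  ring_width_q = 0.02, background = 50,
                                  noise = noise, seed = seed, ...)
  list(detector = detn, calibrant = cal, geometry = geom, frame = frm)
}

random_frame <- function(n = 64, seed = 1, lambda = 80) {
  withr::with_seed(seed, frame(matrix(stats::rpois(n * n, lambda), n, n)))
}

# minimal baseline TIFF writer (independent byte-level construction used
# only as a fixture source for the package's reader)
write_test_tiff <- function(path, vals, bits = 16L) {
  h <- nrow(vals); w <- ncol(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); wr2(42); wr4(8)
  n <- 8L
  wr2(n)
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3) { wr2(value); wr2(0) } else wr4(value)
  }
  data_off <- 8 + 2 + n * 12 + 4
  entry(256, 3, 1, w); entry(257, 3, 1, h); entry(258, 3, 1, bits)
  entry(259, 3, 1, 1); entry(262, 3, 1, 1)
  entry(273, 4, 1, data_off); entry(278, 3, 1, h)
  entry(279, 4, 1, w * h * bits / 8)
  wr4(0)
  writeBin(as.integer(t(vals)), con, size = bits / 8, endian = "little")
  invisible(path)
}
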