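# Built-in processing steps (registered on package load): the standard
# powder/SAXS reduction chain — calibration import, threshold mask,
# detector error model, intensity corrections, normalization, dynamic
# background subtraction, cake remapping, azimuthal integration, text
# export — plus the downstream analysis steps.

num_par <- function(default = NULL, min = NULL, max = NULL, required = FALSE)
  list(type = "numeric", default = default, min = min, max = max,
       required = required)
int_par <- function(default = NULL, min = NULL, max = NULL, required = FALSE)
  list(type = "integer", default = default, min = min, max = max,
       required = required)
chr_par <- function(default = NULL, choices = NULL, required = FALSE)
  list(type = "character", default = default, choices = choices,
       required = required)
lgl_par <- function(default = NULL, required = FALSE)
  list(type = "logical", default = default, required = required)

range_or_null <- function(lo, hi) if (is.null(lo) || is.null(hi)) NULL else c(lo, hi)

register_builtin_steps <- function() {
  register_step("detector_calibration",
    list(file = chr_par(required = TRUE)),
    function(x, p, ctx) x, "frame", "frame", overwrite = TRUE)

  register_step("threshold_mask",
    list(low = num_par(required = TRUE), high = num_par(required = TRUE)),
    function(x, p, ctx) threshold_mask(x, p$low, p$high),
    "frame", "frame", overwrite = TRUE)

  register_step("detector_error",
    list(gain = num_par(default = 1, min = 1e-12)),
    function(x, p, ctx) estimate_errors(x, p$gain),
    "frame", "frame", overwrite = TRUE)

  register_step("intensity_corrections",
    list(solid_angle = lgl_par(default = TRUE),
         polarization = lgl_par(default = FALSE),
         polarization_fraction = num_par(default = 0, min = -1, max = 1)),
    function(x, p, ctx) {
      if (isTRUE(p$solid_angle)) x <- correct_solid_angle(x, ctx$geometry)
      if (isTRUE(p$polarization)) {
        x <- correct_polarization(x, ctx$geometry, p$polarization_fraction)
      }
      x
    }, "frame", "frame", needs_geometry = TRUE, overwrite = TRUE)

  register_step("divide",
    list(value = num_par(), metadata_key = chr_par()),
    function(x, p, ctx) {
      by <- if (!is.null(p$metadata_key)) p$metadata_key else p$value
      if (is.null(by)) stop("divide: give 'value' or 'metadata_key'")
      divide_frame(x, by)
    }, "frame", "frame", overwrite = TRUE)

  register_step("background_subtract",
    list(iterations = int_par(default = 24, min = 0),
         clip_factor = num_par(default = 3, min = 0),
         window = int_par(), n_bins = int_par(default = 512, min = 8)),
    function(x, p, ctx) subtract_radial_background(
      x, ctx$geometry, iterations = p$iterations, clip_factor = p$clip_factor,
      window = p$window, n_bins = p$n_bins),
    "frame", "frame", needs_geometry = TRUE, overwrite = TRUE)

  register_step("cake_remap",
    list(n_radial = int_par(default = 500, min = 2),
         n_azimuthal = int_par(default = 360, min = 1),
         radial_unit = chr_par(default = "q",
                               choices = c("q", "two_theta", "d")),
         splitting = chr_par(default = "none", choices = c("none", "bbox")),
         radial_lo = num_par(), radial_hi = num_par(),
         azimuth_lo = num_par(default = -180), azimuth_hi = num_par(default = 180)),
    function(x, p, ctx) cake_remap(
      x, ctx$geometry, n_radial = p$n_radial, n_azimuthal = p$n_azimuthal,
      radial_unit = p$radial_unit, splitting = p$splitting,
      radial_range = range_or_null(p$radial_lo, p$radial_hi),
      azimuth_range = c(p$azimuth_lo, p$azimuth_hi)),
    "frame", "cake", needs_geometry = TRUE, overwrite = TRUE)

  register_step("azimuthal_integration",
    list(n_bins = int_par(default = 500, min = 2),
         radial_unit = chr_par(default = "q",
                               choices = c("q", "two_theta", "d")),
         splitting = chr_par(default = "none", choices = c("none", "bbox")),
         radial_lo = num_par(), radial_hi = num_par(),
         azimuth_lo = num_par(), azimuth_hi = num_par()),
    function(x, p, ctx) integrate_azimuthal(
      x, ctx$geometry, n_bins = p$n_bins, radial_unit = p$radial_unit,
      splitting = p$splitting,
      radial_range = range_or_null(p$radial_lo, p$radial_hi),
      azimuth_range = range_or_null(p$azimuth_lo, p$azimuth_hi)),
    "frame", "profile", needs_geometry = TRUE, overwrite = TRUE)

  register_step("export_text",
    list(directory = chr_par()),
    function(x, p, ctx) x, "profile", "profile", overwrite = TRUE)

  register_step("azimuthal_profile",
    list(q_lo = num_par(required = TRUE), q_hi = num_par(required = TRUE)),
    function(x, p, ctx) azimuthal_profile(x, c(p$q_lo, p$q_hi)),
    "cake", "azprofile", overwrite = TRUE)

  register_step("orientation_metrics",
    list(floor_percentile = num_par(default = 5, min = 0, max = 50)),
    function(x, p, ctx) {
      om <- orientation_metrics(x, p$floor_percentile)
      c(degree = om$degree, direction = om$direction,
        total_intensity = om$total_intensity)
    }, "azprofile", "scalars", overwrite = TRUE)

  register_step("fit_peak",
    list(window_lo = num_par(required = TRUE),
         window_hi = num_par(required = TRUE),
         shape = chr_par(default = "gaussian",
                         choices = c("gaussian", "pseudo_voigt"))),
    function(x, p, ctx) {
      pr <- fit_peak(x, c(p$window_lo, p$window_hi), p$shape)
      c(centre = pr$centre, fwhm = pr$fwhm, area = pr$area,
        centre_err = pr$uncertainties[["centre"]],
        fwhm_err = pr$uncertainties[["fwhm"]],
        success = as.numeric(pr$success))
    }, "profile", "scalars", overwrite = TRUE)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_steps()
}
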