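# NeXus/HDF5 persistence (via rhdf5): calibration files, processed-data
# files with NXprocess provenance, plus ASCII xy export and a minimal
# baseline TIFF reader for single-frame input.

.nexus_version <- "1.0"

h5_attr <- function(file, name, attr, value) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  rhdf5::h5writeAttribute(value, obj, attr)
}

h5_mkgroup <- function(file, name, nx_class = NULL) {
  rhdf5::h5createGroup(file, name)
  if (!is.null(nx_class)) h5_attr(file, name, "NX_class", nx_class)
}

#' Save / load a calibration result as a NeXus file
#'
#' The calibration NeXus layout stores, under `/entry/calibration`:
#' `distance` (mm), `beam_centre_fast` / `beam_centre_slow` (pixels),
#' `tilt_pitch` / `tilt_yaw` (deg), `wavelength` (Angstrom), per-parameter
#' `uncertainty_*` datasets, the `fixed_parameters`, fit-quality numbers,
#' and the provenance of the calibration: the calibrant and routine
#' strings verbatim, plus the detector description (so the round trip is
#' lossless).
#'
#' @param result A `calibration_result`.
#' @param path Output / input file path.
#' @return `load_calibration()` returns the `calibration_result`;
#'   `save_calibration()` returns `path` invisibly.
#' @export
save_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_mkgroup(path, "/entry", "NXentry")
  h5_mkgroup(path, "/entry/calibration")
  base <- "/entry/calibration"
  g <- result$geometry
  for (nm in .geom_par_names) {
    rhdf5::h5write(g[[nm]], path, file.path(base, nm))
  }
  h5_attr(path, file.path(base, "distance"), "units", "mm")
  h5_attr(path, file.path(base, "wavelength"), "units", "angstrom")
  for (nm in names(result$uncertainties)) {
    rhdf5::h5write(result$uncertainties[[nm]], path,
                   file.path(base, paste0("uncertainty_", nm)))
  }
  rhdf5::h5write(if (length(result$fixed_parameters)) result$fixed_parameters
                 else "", path, file.path(base, "fixed_parameters"))
  rhdf5::h5write(result$residual_rms_q, path, file.path(base, "residual_rms_q"))
  rhdf5::h5write(as.integer(result$n_points), path, file.path(base, "n_points"))
  rhdf5::h5write(as.integer(result$n_rings), path, file.path(base, "n_rings"))
  rhdf5::h5write(result$routine, path, file.path(base, "routine"))
  rhdf5::h5write(as.character(result$calibrant_name), path,
                 file.path(base, "calibrant"))
  det <- g$detector
  h5_mkgroup(path, file.path(base, "detector"))
  for (nm in c("n_slow", "n_fast", "pixel_size_slow", "pixel_size_fast",
               "saturation")) {
    rhdf5::h5write(det[[nm]], path, file.path(base, "detector", nm))
  }
  rhdf5::h5write(matrix(as.integer(det$static_mask), nrow(det$static_mask)),
                 path, file.path(base, "detector", "static_mask"))
  h5_attr(path, "/entry", "format_version", .nexus_version)
  invisible(path)
}

h5_read_or_stop <- function(path, name, contents) {
  if (!name %in% contents) {
    stop(sprintf("calibration file is missing required field '%s'", name))
  }
  rhdf5::h5read(path, name)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop("no such calibration file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_ <- rhdf5::h5ls(path)
  contents <- file.path(ls_$group, ls_$name)
  contents <- sub("^//", "/", contents)
  base <- "/entry/calibration"
  vals <- lapply(stats::setNames(.geom_par_names, .geom_par_names),
                 function(nm) as.numeric(
                   h5_read_or_stop(path, file.path(base, nm), contents)))
  detbase <- file.path(base, "detector")
  mask_raw <- h5_read_or_stop(path, file.path(detbase, "static_mask"), contents)
  det <- detector_spec(
    n_slow = as.integer(h5_read_or_stop(path, file.path(detbase, "n_slow"), contents)),
    n_fast = as.integer(h5_read_or_stop(path, file.path(detbase, "n_fast"), contents)),
    pixel_size_slow = as.numeric(h5_read_or_stop(path, file.path(detbase, "pixel_size_slow"), contents)),
    pixel_size_fast = as.numeric(h5_read_or_stop(path, file.path(detbase, "pixel_size_fast"), contents)),
    static_mask = matrix(as.logical(mask_raw), nrow(mask_raw)),
    saturation = as.numeric(h5_read_or_stop(path, file.path(detbase, "saturation"), contents)))
  geom <- diffraction_geometry(
    distance = vals$distance, beam_centre_fast = vals$beam_centre_fast,
    beam_centre_slow = vals$beam_centre_slow, tilt_pitch = vals$tilt_pitch,
    tilt_yaw = vals$tilt_yaw, wavelength = vals$wavelength, detector = det)
  unc_names <- grep("uncertainty_", basename(contents), value = TRUE)
  unc <- vapply(unc_names, function(nm)
    as.numeric(rhdf5::h5read(path, file.path(base, nm))), 0)
  names(unc) <- sub("^uncertainty_", "", unc_names)
  fixed <- as.character(h5_read_or_stop(path, file.path(base, "fixed_parameters"), contents))
  fixed <- fixed[nzchar(fixed)]
  new_calibration_result(
    geom, unc[order(match(names(unc), .geom_par_names))], fixed,
    as.numeric(h5_read_or_stop(path, file.path(base, "residual_rms_q"), contents)),
    as.integer(h5_read_or_stop(path, file.path(base, "n_points"), contents)),
    as.integer(h5_read_or_stop(path, file.path(base, "n_rings"), contents)),
    as.character(h5_read_or_stop(path, file.path(base, "routine"), contents)),
    as.character(h5_read_or_stop(path, file.path(base, "calibrant"), contents)))
}

# --- processed-data NeXus output -------------------------------------------

write_nxdata <- function(path, group, data, axes = NULL, errors = NULL) {
  h5_mkgroup(path, group, "NXdata")
  rhdf5::h5write(data, path, file.path(group, "data"))
  h5_attr(path, group, "signal", "data")
  axis_names <- character(0)
  if (!is.null(axes)) {
    for (ax in axes) {
      if (is.null(ax)) { axis_names <- c(axis_names, "."); next }
      axis_names <- c(axis_names, ax$name)
      rhdf5::h5write(ax$values, path, file.path(group, ax$name))
      if (!is.null(ax$units)) {
        h5_attr(path, file.path(group, ax$name), "units", ax$units)
      }
    }
    h5_attr(path, group, "axes", axis_names)
  }
  if (!is.null(errors)) rhdf5::h5write(errors, path, file.path(group, "errors"))
}

#' Write processed results to a NeXus file
#'
#' Output layout: `/entry` (NXentry) holds `/entry/result` (NXdata with
#' signal `"data"`, axis datasets named in the `axes` attribute, and an
#' `"errors"` dataset), one `/entry/intermediate/<n>-<step_name>` NXdata
#' group per saved intermediate, and `/entry/process` (NXprocess) with the
#' program name/version, the input reference, the verbatim chain
#' serialization and one sequenced NXnote per step holding that step's
#' parameter record.
#'
#' @param path Output file.
#' @param result List with `data`, `axes`, optional `errors`.
#' @param provenance List with `input`, `chain_json`, `steps` (list of
#'   `list(name, params_json)`), optional `calibration` path.
#' @param intermediates Named list of result-like lists; names are
#'   `<n>-<step_name>`.
#' @param extra Named list of additional result-like lists written as
#'   sibling NXdata groups under `/entry` (e.g. per-scalar maps).
#' @return `path`, invisibly.
#' @export
write_processed <- function(path, result, provenance, intermediates = list(),
                            extra = list()) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_mkgroup(path, "/entry", "NXentry")
  h5_attr(path, "/entry", "format_version", .nexus_version)
  write_nxdata(path, "/entry/result", result$data, result$axes, result$errors)
  if (length(intermediates)) {
    h5_mkgroup(path, "/entry/intermediate")
    for (nm in names(intermediates)) {
      it <- intermediates[[nm]]
      write_nxdata(path, file.path("/entry/intermediate", nm),
                   it$data, it$axes, it$errors)
    }
  }
  for (nm in names(extra)) {
    it <- extra[[nm]]
    write_nxdata(path, file.path("/entry", nm), it$data, it$axes, it$errors)
  }
  h5_mkgroup(path, "/entry/process", "NXprocess")
  rhdf5::h5write("diffractr", path, "/entry/process/program")
  rhdf5::h5write(as.character(utils::packageVersion("diffractr")), path,
                 "/entry/process/version")
  rhdf5::h5write(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), path,
                 "/entry/process/date")
  rhdf5::h5write(as.character(provenance$input %||% ""), path,
                 "/entry/process/input")
  rhdf5::h5write(provenance$chain_json, path, "/entry/process/chain")
  if (!is.null(provenance$calibration)) {
    rhdf5::h5write(as.character(provenance$calibration), path,
                   "/entry/process/calibration_file")
  }
  for (i in seq_along(provenance$steps)) {
    st <- provenance$steps[[i]]
    gname <- sprintf("/entry/process/%d_%s", i - 1L, st$name)
    h5_mkgroup(path, gname, "NXnote")
    rhdf5::h5write(st$params_json, path, file.path(gname, "data"))
    rhdf5::h5write(st$name, path, file.path(gname, "description"))
    rhdf5::h5write(as.integer(i - 1L), path, file.path(gname, "sequence_index"))
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_hdf5_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  sig <- readBin(con, "raw", 8)
  length(sig) == 8 &&
    identical(sig, as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a)))
}

is_tiff_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  sig <- readBin(con, "raw", 4)
  identical(sig[1:2], as.raw(c(0x49, 0x49))) &&
    identical(sig[3:4], as.raw(c(0x2a, 0x00))) ||
  identical(sig[1:2], as.raw(c(0x4d, 0x4d))) &&
    identical(sig[3:4], as.raw(c(0x00, 0x2a)))
}

# minimal baseline TIFF reader: uncompressed, grayscale, strip-based,
# 8/16/32-bit unsigned integer or 32/64-bit float, little or big endian
read_tiff_frame <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  endian <- if (raw_all[1] == as.raw(0x49)) "little" else "big"
  rint <- function(off, size, n = 1, signed = FALSE) {
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n,
            size = size, endian = endian, signed = signed)
  }
  ruint32 <- function(off, n = 1) {
    lo <- rint(off, 2, 2 * n, signed = FALSE)
    if (endian == "little") lo[seq(1, 2 * n, 2)] + 65536 * lo[seq(2, 2 * n, 2)]
    else 65536 * lo[seq(1, 2 * n, 2)] + lo[seq(2, 2 * n, 2)]
  }
  ifd <- ruint32(4)
  n_entries <- rint(ifd, 2, signed = FALSE)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- ifd + 2 + (k - 1) * 12
    tag <- rint(e, 2, signed = FALSE)
    type <- rint(e + 2, 2, signed = FALSE)
    count <- ruint32(e + 4)
    val <- if (type == 3 && count <= 2) rint(e + 8, 2, count, signed = FALSE)[1:count]
           else if (count == 1) ruint32(e + 8)
           else ruint32(ruint32(e + 8), count)
    tags[[as.character(tag)]] <- val
  }
  gt <- function(t, default = NULL) tags[[as.character(t)]] %||% default
  width <- gt(256); height <- gt(257)
  bits <- gt(258, 8); fmt <- gt(339, 1)  # 1 uint, 2 int, 3 float
  comp <- gt(259, 1)
  if (is.null(width) || is.null(height)) stop("malformed TIFF: no dimensions")
  if (comp != 1) stop("only uncompressed TIFF is supported")
  offsets <- gt(273); counts_ <- gt(279)
  rps <- gt(278, height)
  bytes <- unlist(lapply(seq_along(offsets), function(s) {
    raw_all[(offsets[s] + 1):(offsets[s] + counts_[s])]
  }))
  npix <- width * height
  vals <- if (fmt == 3) {
    readBin(bytes, "double", n = npix, size = bits / 8, endian = endian)
  } else if (bits == 8) {
    as.integer(readBin(bytes, "raw", n = npix))
  } else if (bits == 16) {
    readBin(bytes, "integer", n = npix, size = 2, endian = endian,
            signed = FALSE)
  } else {
    v <- readBin(bytes, "integer", n = npix, size = 4, endian = endian)
    ifelse(v < 0, v + 2^32, v)
  }
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

#' Read a dataset for processing
#'
#' HDF5/NeXus input: reads the named dataset (or the first NXdata signal
#' found), honouring `signal` and `axes` attributes; detector axes are the
#' trailing dimensions. TIFF input (baseline grayscale, uncompressed) is
#' read as a rank-2 [scan_dataset()] with pixel-index axes.
#'
#' @param path Input file.
#' @param dataset_path Optional HDF5 dataset path.
#' @param signal_rank Trailing signal rank (2 for images, 1 for profiles).
#' @return A [scan_dataset()].
#' @export
read_dataset <- function(path, dataset_path = NULL, signal_rank = 2L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is_tiff_file(path)) {
    img <- read_tiff_frame(path)
    return(scan_dataset(img, axes = list(
      list(name = "slow", values = seq_len(nrow(img)) - 1, units = "pixel"),
      list(name = "fast", values = seq_len(ncol(img)) - 1, units = "pixel")),
      signal_rank = 2L, metadata = list(source = path)))
  }
  if (!is_hdf5_file(path)) stop("unknown input format (not HDF5/NeXus or TIFF): ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_ <- rhdf5::h5ls(path)
  full <- sub("^//", "/", file.path(ls_$group, ls_$name))
  if (is.null(dataset_path)) {
    # prefer the canonical result group, else first group with a signal
    grp_candidates <- full[ls_$otype == "H5I_GROUP"]
    if ("/entry/result" %in% grp_candidates) {
      grp_candidates <- c("/entry/result",
                          setdiff(grp_candidates, "/entry/result"))
    }
    dataset_path <- NULL
    for (g in grp_candidates) {
      at <- tryCatch(rhdf5::h5readAttributes(path, g), error = function(e) list())
      if (!is.null(at$signal)) { dataset_path <- file.path(g, at$signal); break }
    }
    if (is.null(dataset_path)) stop("no NXdata signal found; give dataset_path")
  }
  if (!dataset_path %in% full) stop("missing signal dataset: ", dataset_path)
  dat <- rhdf5::h5read(path, dataset_path)
  grp <- dirname(dataset_path)
  at <- tryCatch(rhdf5::h5readAttributes(path, grp), error = function(e) list())
  axes <- NULL
  if (!is.null(at$axes)) {
    axnames <- as.character(at$axes)
    axes <- lapply(seq_along(axnames), function(i) {
      nm <- axnames[i]
      if (nm == ".") return(NULL)
      p <- file.path(grp, nm)
      if (!p %in% full) return(NULL)
      v <- as.numeric(rhdf5::h5read(path, p))
      ats <- tryCatch(rhdf5::h5readAttributes(path, p), error = function(e) list())
      list(name = nm, values = v,
           units = if (is.null(ats$units)) NULL else as.character(ats$units))
    })
    if (length(axes) != length(dim(dat))) axes <- NULL
  }
  errs <- NULL
  ep <- file.path(grp, "errors")
  if (ep %in% full) errs <- rhdf5::h5read(path, ep)
  md <- list(source = path, dataset = dataset_path)
  if (!is.null(errs)) md$errors <- errs
  scan_dataset(dat, axes = axes,
               signal_rank = min(signal_rank, length(dim(dat))),
               metadata = md)
}

#' Export radial profiles to ASCII xy files
#'
#' Writes one text file per frame: a `#`-prefixed header (axis name and
#' unit plus a provenance one-liner) followed by 2 or 3 columns (radial,
#' intensity and, when present, error). Multi-frame input gets a
#' zero-padded frame suffix per file.
#'
#' @param profiles A single `radial_profile` or a list of them.
#' @param path Output file path; for multiple frames the frame number is
#'   inserted before the extension.
#' @param provenance One-line provenance comment.
#' @return Character vector of files written, invisibly.
#' @export
export_ascii <- function(profiles, path, provenance = "diffractr export") {
  single <- inherits(profiles, "radial_profile")
  if (single) profiles <- list(profiles)
  n <- length(profiles)
  ext <- tools::file_ext(path)
  stem <- if (nzchar(ext)) sub(paste0("\\.", ext, "$"), "", path) else path
  width <- max(4, nchar(as.character(n)))
  files <- character(n)
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    unit <- switch(radial_unit(p) %||% "q",
                   q = "1/angstrom", two_theta = "deg", d = "angstrom")
    f <- if (single && n == 1) path else {
      sprintf("%s_%0*d%s", stem, width, i, if (nzchar(ext)) paste0(".", ext) else "")
    }
    hdr <- c(sprintf("# %s", provenance),
             sprintf("# columns: %s [%s]  intensity%s",
                     radial_unit(p) %||% "q", unit,
                     if (all(is.na(p$error))) "" else "  error"))
    cols <- if (all(is.na(p$error))) cbind(p$radial, p$intensity)
            else cbind(p$radial, p$intensity, p$error)
    con <- file(f, "wt")
    writeLines(hdr, con)
    utils::write.table(cols, con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    close(con)
    files[i] <- f
  }
  invisible(files)
}
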