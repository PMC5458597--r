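# Built-in calibration standards, generated from published cubic lattice
# parameters rather than hard-coded d lists, so the provenance of every
# reference number is auditable.
#
#   CeO2 (NIST SRM 674b): fluorite structure, Fm-3m, a = 5.411651 A
#     (SRM 674b certificate of analysis). Allowed hkl: h,k,l all even or
#     all odd (F-centring).
#   Si (NIST SRM 640c): diamond structure, Fd-3m, a = 5.4311946 A
#     (SRM 640c certificate). Allowed hkl: all odd, or all even with
#     h + k + l = 4n.
.builtin_calibrants <- list(
  CeO2_SRM674b = list(a = 5.411651, structure = "fcc"),
  Si_SRM640c   = list(a = 5.4311946, structure = "diamond")
)

cubic_d_spacings <- function(a, structure = c("fcc", "diamond", "simple"),
                             n_max = 50L, hkl_max = 12L) {
  structure <- match.arg(structure)
  hkl <- expand.grid(h = 0:hkl_max, k = 0:hkl_max, l = 0:hkl_max)
  hkl <- hkl[rowSums(hkl) > 0, ]
  keep <- switch(structure,
    simple = rep(TRUE, nrow(hkl)),
    fcc = with(hkl, (h %% 2 == 0 & k %% 2 == 0 & l %% 2 == 0) |
                    (h %% 2 == 1 & k %% 2 == 1 & l %% 2 == 1)),
    diamond = with(hkl, (h %% 2 == 1 & k %% 2 == 1 & l %% 2 == 1) |
                        (h %% 2 == 0 & k %% 2 == 0 & l %% 2 == 0 &
                         (h + k + l) %% 4 == 0)))
  hkl <- hkl[keep, ]
  s2 <- hkl$h^2 + hkl$k^2 + hkl$l^2
  # one label per distinct s^2; canonical hkl = largest h >= k >= l
  ord <- order(s2, -hkl$h, -hkl$k, -hkl$l)
  hkl <- hkl[ord, ]; s2 <- s2[ord]
  first <- !duplicated(s2)
  hkl <- hkl[first, ]; s2 <- s2[first]
  hkl <- hkl[order(s2), ]; s2 <- sort(s2)
  d <- a / sqrt(s2)
  n <- min(n_max, length(d))
  list(d = d[seq_len(n)],
       labels = sprintf("%d%d%d", hkl$h, hkl$k, hkl$l)[seq_len(n)])
}

new_calibrant <- function(name, d_spacings, labels = NULL) {
  d_spacings <- as.numeric(d_spacings)
  if (any(!is.finite(d_spacings)) || any(d_spacings <= 0)) {
    stop("calibrant d-spacings must be finite and positive")
  }
  if (is.unsorted(rev(d_spacings), strictly = TRUE)) {
    stop("calibrant d-spacings must be strictly decreasing")
  }
  if (length(d_spacings) > 1 && any(-diff(d_spacings) < 1e-6)) {
    stop("duplicate d-spacings (within 1e-6 A) in calibrant")
  }
  if (!is.null(labels) && length(labels) != length(d_spacings)) {
    stop("labels must match d_spacings in length")
  }
  structure(list(name = name, d_spacings = d_spacings, labels = labels),
            class = "calibrant")
}

#' Load a calibration standard
#'
#' Built-in standards (`"CeO2_SRM674b"`, `"Si_SRM640c"`) are generated from
#' their published cubic lattice parameters and selection rules. Any other
#' argument is treated as a path to a text line list: `#` comments, one
#' d-spacing in Angstrom per line, optional second column with an hkl label.
#'
#' @param name_or_path Built-in name or file path.
#' @return An object of class `calibrant` with strictly decreasing
#'   `d_spacings` (Angstrom) and optional `labels`.
#' @export
load_calibrant <- function(name_or_path) {
  if (name_or_path %in% names(.builtin_calibrants)) {
    b <- .builtin_calibrants[[name_or_path]]
    dd <- cubic_d_spacings(b$a, b$structure)
    return(new_calibrant(name_or_path, dd$d, dd$labels))
  }
  if (!file.exists(name_or_path)) {
    stop(sprintf("unknown calibrant '%s' (not a built-in, not a file); built-ins: %s",
                 name_or_path, paste(names(.builtin_calibrants), collapse = ", ")))
  }
  lines <- readLines(name_or_path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("calibrant file contains no d-spacings")
  parts <- strsplit(lines, "[[:space:],]+")
  d <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1]), 0))
  if (any(is.na(d))) stop("calibrant file has non-numeric d-spacing lines")
  labels <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  if (all(is.na(labels))) labels <- NULL
  new_calibrant(basename(name_or_path), d, labels)
}

#' @export
format.calibrant <- function(x, ...) {
  sprintf("<calibrant> %s: %d lines, d in [%.4f, %.4f] A",
          x$name, length(x$d_spacings), min(x$d_spacings), max(x$d_spacings))
}

#' @export
print.calibrant <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Reachable calibrant rings at a given wavelength
#'
#' Applies Bragg's law `lambda = 2 d sin(theta)`: only reflections with
#' `lambda < 2d` and `two_theta <= two_theta_max` are returned, with
#' `q = 2 pi / d` strictly increasing.
#'
#' @param cal A [load_calibrant()] object.
#' @param wavelength Wavelength in Angstrom (> 0).
#' @param two_theta_max Upper scattering-angle cutoff in degrees.
#' @return A tibble with columns `ring`, `label`, `d` (A), `q` (1/A),
#'   `two_theta` (deg); zero rows when no reflection is reachable.
#' @export
ring_positions <- function(cal, wavelength, two_theta_max = 180) {
  stopifnot(inherits(cal, "calibrant"), wavelength > 0)
  d <- cal$d_spacings
  reach <- wavelength < 2 * d
  tt <- rep(NA_real_, length(d))
  tt[reach] <- rad2deg(2 * asin(wavelength / (2 * d[reach])))
  keep <- reach & tt <= two_theta_max
  tibble::tibble(
    ring = seq_along(d)[keep],
    label = if (is.null(cal$labels)) NA_character_ else cal$labels[keep],
    d = d[keep],
    q = 2 * pi / d[keep],
    two_theta = tt[keep])
}
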