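#' A single 2D detector frame
#'
#' Bundles a count matrix with an optional per-pixel error map, an exclusion
#' mask and free-form metadata (monitor readings, frame axes). Masked pixels
#' (`mask == TRUE`) never contribute to any reduction.
#'
#' @param counts Numeric matrix, dim `c(n_slow, n_fast)`.
#' @param errors Optional numeric matrix of the same dim, all values >= 0
#'   where unmasked.
#' @param mask Logical matrix of the same dim; defaults to all-`FALSE`.
#' @param metadata Named list.
#' @return An object of class `frame`.
#' @export
frame <- function(counts, errors = NULL, mask = NULL, metadata = list()) {
  stopifnot(is.matrix(counts))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  stopifnot(is.logical(mask), identical(dim(mask), dim(counts)))
  if (!is.null(errors)) {
    stopifnot(identical(dim(errors), dim(counts)))
    if (any(errors[!mask & is.finite(errors)] < 0)) {
      stop("frame errors must be >= 0 on unmasked pixels")
    }
  }
  structure(list(counts = counts, errors = errors, mask = mask,
                 metadata = metadata),
            class = "frame")
}

#' @export
format.frame <- function(x, ...) {
  sprintf("<frame> %d x %d px, %d masked, errors: %s",
          nrow(x$counts), ncol(x$counts), sum(x$mask),
          if (is.null(x$errors)) "absent" else "present")
}

#' @export
print.frame <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' An N-dimensional scan stack
#'
#' Holds an N-d data array whose *last* `signal_rank` axes are the detector
#' (or profile) axes; the leading axes are scan axes (time, temperature,
#' sample-stage coordinates) whose coordinate arrays travel with the data.
#'
#' @param data Numeric array.
#' @param axes List, one entry per array dimension, each either `NULL` or a
#'   list with `name`, `values` (length = dim) and optional `units`.
#' @param signal_rank Number of trailing detector/profile axes (1 or 2).
#' @param metadata Named list.
#' @return An object of class `scan_dataset`.
#' @export
scan_dataset <- function(data, axes = NULL, signal_rank = 2L,
                         metadata = list()) {
  d <- dim(data)
  if (is.null(d)) { data <- array(data, length(data)); d <- dim(data) }
  stopifnot(signal_rank %in% c(1L, 2L), length(d) >= signal_rank)
  if (is.null(axes)) axes <- vector("list", length(d))
  stopifnot(length(axes) == length(d))
  for (i in seq_along(axes)) {
    if (!is.null(axes[[i]]) && length(axes[[i]]$values) != d[i]) {
      stop(sprintf("axis %d length %d does not match dim %d",
                   i, length(axes[[i]]$values), d[i]))
    }
  }
  structure(list(data = data, axes = axes, signal_rank = as.integer(signal_rank),
                 metadata = metadata),
            class = "scan_dataset")
}

#' @export
format.scan_dataset <- function(x, ...) {
  sprintf("<scan_dataset> dim (%s), signal rank %d, scan rank %d",
          paste(dim(x$data), collapse = ", "), x$signal_rank, scan_rank(x))
}

#' @export
print.scan_dataset <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @rdname scan_dataset
#' @param x A `scan_dataset`.
#' @export
scan_rank <- function(x) length(dim(x$data)) - x$signal_rank

# Extract the i-th frame (linear index over scan cells, first scan axis
# fastest) as a `frame` or, for signal_rank 1, a numeric vector.
scan_slice <- function(x, i) {
  d <- dim(x$data)
  sr <- x$signal_rank
  nscan <- length(d) - sr
  if (nscan == 0) {
    sig <- x$data
  } else {
    scan_dims <- d[seq_len(nscan)]
    idx <- arrayInd(i, scan_dims)
    args <- c(as.list(idx[1, ]), rep(list(quote(expr = )), sr), list(drop = FALSE))
    sig <- do.call(`[`, c(list(x$data), args))
    dim(sig) <- d[nscan + seq_len(sr)]
  }
  if (sr == 1L) as.vector(sig) else sig
}

n_scan_cells <- function(x) {
  d <- dim(x$data)
  nscan <- length(d) - x$signal_rank
  if (nscan == 0) 1L else prod(d[seq_len(nscan)])
}
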