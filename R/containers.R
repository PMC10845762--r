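#' Sinogram container
#'
#' A sinogram holds the line integrals of the attenuation map, indexed
#' `(detector bin, view)`, together with its acquisition geometry and a
#' validity mask. Entries where `valid` is `FALSE` (removed views, metal
#' tracks) are treated as undefined by every consumer; reconstruction
#' refuses them until completion has filled them in.
#'
#' @param values numeric matrix of dimension `n_bins x n_views`.
#' @param geometry a [scan_geometry()] whose detector/view counts match
#'   `values`.
#' @param valid optional logical matrix of the same shape; defaults to all
#'   `TRUE`.
#' @return An object of class `sinogram` with fields `values`, `geometry`
#'   and `valid`.
#' @export
sinogram <- function(values, geometry, valid = NULL) {
  stopifnot(is.matrix(values), inherits(geometry, "scan_geometry"))
  if (nrow(values) != geometry$n_bins || ncol(values) != geometry$n_views) {
    stop("sinogram shape ", nrow(values), "x", ncol(values),
         " does not match geometry (", geometry$n_bins, " bins x ",
         geometry$n_views, " views)", call. = FALSE)
  }
  if (is.null(valid)) {
    valid <- matrix(TRUE, nrow(values), ncol(values))
  }
  stopifnot(is.logical(valid), all(dim(valid) == dim(values)))
  if (any(!is.finite(values[valid]))) {
    stop("sinogram contains non-finite values at valid entries", call. = FALSE)
  }
  structure(list(values = values, geometry = geometry, valid = valid),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  n_invalid <- sum(!x$valid)
  cat(sprintf("sinogram: %d bins x %d views, %d invalid entr%s\n",
              nrow(x$values), ncol(x$values), n_invalid,
              if (n_invalid == 1) "y" else "ies"))
  print(x$geometry)
  invisible(x)
}

#' Image slice container
#'
#' A 2-D attenuation map on the reconstruction grid: the unit that the
#' networks and the evaluation metrics consume. Values are linear
#' attenuation per pixel in arbitrary consistent units; negative values are
#' permitted (filtered backprojection produces them) and are never clipped,
#' because the metrics operate on raw values.
#'
#' @param values square numeric matrix (`image_size x image_size`).
#' @param geometry a [scan_geometry()] with matching `image_size`.
#' @return An object of class `image_slice`.
#' @export
image_slice <- function(values, geometry) {
  stopifnot(is.matrix(values), inherits(geometry, "scan_geometry"))
  if (nrow(values) != geometry$image_size ||
      ncol(values) != geometry$image_size) {
    stop("image shape ", nrow(values), "x", ncol(values),
         " does not match geometry grid (", geometry$image_size, " px)",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  structure(list(values = values, geometry = geometry),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("image_slice: %d x %d px, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

as_values <- function(x) {
  if (inherits(x, "image_slice") || inherits(x, "sinogram")) x$values else x
}
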