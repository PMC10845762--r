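#' Segment metal in the image domain by thresholding
#'
#' Marks every pixel whose attenuation is greater than or equal to the
#' threshold as metal (the boundary case exactly at the threshold is
#' included) and records the original pixel values on that support, so the
#' metal can later be reinserted verbatim by [reinsert_metal()]. An empty
#' mask is a valid outcome.
#'
#' The default threshold used by the pipeline is the midpoint between the
#' simulation's maximum soft-tissue attenuation and the metal attenuation
#' (see [pipeline_config()]), which guarantees exact segmentation on
#' synthetic data; on real data the threshold is data-dependent and must
#' be chosen by the user.
#'
#' @param image an [image_slice()].
#' @param threshold finite attenuation threshold.
#' @return An object of class `metal_mask`: list with `support` (logical
#'   matrix), `metal_values` (numeric matrix, `NA` off support) and
#'   `geometry`.
#' @export
segment_metal <- function(image, threshold) {
  stopifnot(inherits(image, "image_slice"),
            is.numeric(threshold), length(threshold) == 1,
            is.finite(threshold))
  support <- image$values >= threshold
  vals <- matrix(NA_real_, nrow(support), ncol(support))
  vals[support] <- image$values[support]
  structure(list(support = support, metal_values = vals,
                 geometry = image$geometry),
            class = "metal_mask")
}

#' @export
print.metal_mask <- function(x, ...) {
  cat(sprintf("metal_mask: %d of %d pixels\n", sum(x$support),
              length(x$support)))
  invisible(x)
}

#' Locate the metal track in the sinogram domain
#'
#' Forward-projects the metal-only image (the mask's values on its support,
#' zero elsewhere) and marks every sinogram bin whose line integral exceeds
#' `trace_threshold` as part of the metal track. By default the track is
#' dilated by one bin along the detector direction to absorb
#' partial-volume bins at the track edges, since threshold-based metal
#' extraction is inherently approximate.
#'
#' @param mask a [segment_metal()] result (or any `metal_mask`).
#' @param geometry a [scan_geometry()]; must match the mask's grid.
#' @param trace_threshold line-integral threshold above which a bin belongs
#'   to the track. Default `1e-9` (zero plus a numerical epsilon).
#' @param dilate integer >= 0: bins of dilation along the detector
#'   direction (default 1).
#' @return An object of class `metal_trace`: list with `support` (logical
#'   `n_bins x n_views` matrix) and `geometry`. Empty iff the mask is
#'   empty; when the mask is non-empty, every view has a non-empty track.
#' @export
compute_metal_trace <- function(mask, geometry, trace_threshold = 1e-9,
                                dilate = 1L) {
  stopifnot(inherits(mask, "metal_mask"),
            inherits(geometry, "scan_geometry"), dilate >= 0)
  if (nrow(mask$support) != geometry$image_size) {
    stop("metal mask grid (", nrow(mask$support),
         " px) does not match geometry (", geometry$image_size, " px)",
         call. = FALSE)
  }
  metal_img <- matrix(0, nrow(mask$support), ncol(mask$support))
  metal_img[mask$support] <- mask$metal_values[mask$support]
  sino <- cpp_forward_project(metal_img, view_angles(geometry),
                              geometry$n_bins, geometry$bin_spacing,
                              geometry$pixel_size)
  supp <- sino > trace_threshold
  if (dilate > 0 && any(supp)) {
    for (d in seq_len(dilate)) {
      up <- rbind(supp[-1, , drop = FALSE], FALSE)
      down <- rbind(FALSE, supp[-nrow(supp), , drop = FALSE])
      supp <- supp | up | down
    }
  }
  structure(list(support = supp, geometry = geometry),
            class = "metal_trace")
}

#' @export
print.metal_trace <- function(x, ...) {
  cat(sprintf("metal_trace: %d of %d bins\n", sum(x$support),
              length(x$support)))
  invisible(x)
}

#' Remove the metal track from a sinogram
#'
#' Flags every bin on the trace support as invalid. Values are left
#' untouched but are treated as undefined by all consumers until the
#' sinogram is completed.
#'
#' @param sino a [sinogram()].
#' @param trace a [compute_metal_trace()] result with matching shape.
#' @return The sinogram with `valid` set to `FALSE` on the trace support.
#' @export
remove_metal <- function(sino, trace) {
  stopifnot(inherits(sino, "sinogram"), inherits(trace, "metal_trace"))
  if (!all(dim(trace$support) == dim(sino$values))) {
    stop("trace shape does not match sinogram", call. = FALSE)
  }
  sino$valid <- sino$valid & !trace$support
  sino
}

#' Reinsert segmented metal into a denoised image
#'
#' Pixelwise selector: the output equals the denoised image everywhere
#' outside the mask support and equals the stored metal values on the
#' support, restoring the extracted metal at its original positions as the
#' final step of the pipeline.
#'
#' @param denoised an [image_slice()].
#' @param mask a `metal_mask` on the same grid.
#' @return An [image_slice()].
#' @export
reinsert_metal <- function(denoised, mask) {
  stopifnot(inherits(denoised, "image_slice"), inherits(mask, "metal_mask"))
  if (!all(dim(mask$support) == dim(denoised$values))) {
    stop("metal mask grid does not match image", call. = FALSE)
  }
  vals <- denoised$values
  vals[mask$support] <- mask$metal_values[mask$support]
  image_slice(vals, denoised$geometry)
}
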