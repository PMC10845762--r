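#' Scan geometry for 2-D parallel-beam acquisition
#'
#' Describes the angular sampling, the detector and the reconstruction grid
#' shared by the projector, the reconstructors and the simulation module.
#' The scanner's cone-beam acquisition is modelled per slice as a 2-D
#' parallel-beam geometry: every algorithmic stage (metal extraction, angular
#' interpolation, the networks, the metrics) operates slice-wise, so nothing
#' downstream depends on the third dimension.
#'
#' Coordinate conventions (used consistently by all operators):
#' image pixel `(1, 1)` is the top-left corner; the isocenter is the grid
#' center; pixel `(i, j)` has physical coordinates
#' `x = (j - (n + 1) / 2) * pixel_size`, `y = ((n + 1) / 2 - i) * pixel_size`
#' (`y` points up). Detector bin `k` sits at
#' `s = (k - (n_bins + 1) / 2) * bin_spacing`, so `s = 0` is the detector
#' center. View `v` is acquired at angle `(v - 1) * angle_step_deg` degrees,
#' measured counter-clockwise from the `+x` axis; views are ordered by
#' increasing angle. The detector coordinate of a point is
#' `s = x * cos(theta) + y * sin(theta)`.
#'
#' @param n_views number of projection angles (default 360).
#' @param angle_step_deg angular increment in degrees (default 1). For a
#'   full scan `n_views * angle_step_deg` must equal 360.
#' @param n_bins detector bin count (default 180).
#' @param bin_spacing detector bin width, in the same physical units as
#'   `pixel_size` (default 1).
#' @param image_size side length of the square reconstruction grid in
#'   pixels (default 128).
#' @param pixel_size image pixel width in physical units (default 1).
#' @param full_scan if `TRUE` (default) require the views to cover exactly
#'   360 degrees.
#'
#' @return An object of class `scan_geometry`.
#'
#' @details The detector must at least cover the inscribed circle of the
#'   image grid (`n_bins * bin_spacing >= image_size * pixel_size`),
#'   otherwise objects filling the field of view are truncated and an error
#'   is raised. Covering the full image diagonal requires
#'   `n_bins * bin_spacing >= image_size * pixel_size * sqrt(2)`; below that
#'   a warning is emitted because the grid corners fall outside the detector.
#'   Simulated specimens are confined to the inscribed circle, where the
#'   default 180-bin detector is sufficient.
#'
#' @examples
#' geom <- scan_geometry()                  # 128 px grid, 360 views at 1 deg
#' geom90 <- scan_geometry(n_views = 90, angle_step_deg = 4)
#' @export
scan_geometry <- function(n_views = 360, angle_step_deg = 1, n_bins = 180,
                          bin_spacing = 1, image_size = 128, pixel_size = 1,
                          full_scan = TRUE) {
  stopifnot(n_views >= 1, angle_step_deg > 0, n_bins >= 2,
            bin_spacing > 0, image_size >= 2, pixel_size > 0)
  if (full_scan && abs(n_views * angle_step_deg - 360) > 1e-9) {
    stop("full-scan geometry requires n_views * angle_step_deg == 360, got ",
         n_views * angle_step_deg, call. = FALSE)
  }
  if (n_bins * bin_spacing < image_size * pixel_size) {
    stop("detector (", n_bins * bin_spacing,
         " units) does not cover the image field of view (",
         image_size * pixel_size, " units): object support would be truncated",
         call. = FALSE)
  }
  if (n_bins * bin_spacing < image_size * pixel_size * sqrt(2)) {
    # corners of the grid are outside the detector; harmless as long as the
    # object stays inside the inscribed circle (all simulated phantoms do)
    if (isTRUE(getOption("sinomar.warn_diagonal", FALSE))) {
      warning("detector does not cover the image diagonal; ",
              "keep objects inside the inscribed circle", call. = FALSE)
    }
  }
  structure(
    list(n_views = as.integer(n_views),
         angle_step_deg = angle_step_deg,
         n_bins = as.integer(n_bins),
         bin_spacing = bin_spacing,
         image_size = as.integer(image_size),
         pixel_size = pixel_size),
    class = "scan_geometry")
}

#' View angles of a geometry, in radians
#'
#' @param geometry a [scan_geometry()].
#' @return numeric vector of length `n_views`.
#' @export
view_angles <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  (seq_len(geometry$n_views) - 1) * geometry$angle_step_deg * pi / 180
}

#' Detector bin positions of a geometry
#'
#' @param geometry a [scan_geometry()].
#' @return numeric vector of length `n_bins`: the signed detector
#'   coordinate `s` of each bin center (`s = 0` at the detector center).
#' @export
detector_positions <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  (seq_len(geometry$n_bins) - (geometry$n_bins + 1) / 2) * geometry$bin_spacing
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: %d views x %.4g deg | %d bins x %.4g | grid %d px x %.4g\n",
    x$n_views, x$angle_step_deg, x$n_bins, x$bin_spacing,
    x$image_size, x$pixel_size))
  invisible(x)
}

geometry_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}
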