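#' Forward projection (parallel-beam line integrals)
#'
#' Computes the line integrals of an attenuation map along every
#' (detector bin, view) ray of the geometry — the Beer's-law sinogram of
#' the image. Integration follows Joseph's method: rays are traversed along
#' their dominant axis with linear interpolation in the transverse
#' coordinate, which makes the operator linear in the image and accurate to
#' the bilinear pixel model.
#'
#' @param image an [image_slice()] (or a plain matrix if `geometry` is
#'   supplied).
#' @param geometry a [scan_geometry()]; defaults to the image's own.
#' @return A [sinogram()] with all entries valid.
#' @examples
#' geom <- scan_geometry(image_size = 64, n_bins = 96)
#' img <- image_slice(matrix(0, 64, 64), geom)
#' sino <- forward_project(img)        # all-zero sinogram
#' max(abs(sino$values)) == 0
#' @export
forward_project <- function(image, geometry = NULL) {
  if (is.matrix(image)) {
    stopifnot(!is.null(geometry))
    image <- image_slice(image, geometry)
  }
  stopifnot(inherits(image, "image_slice"))
  if (is.null(geometry)) geometry <- image$geometry
  if (nrow(image$values) != geometry$image_size) {
    stop("image grid (", nrow(image$values),
         " px) does not match geometry (", geometry$image_size, " px)",
         call. = FALSE)
  }
  vals <- cpp_forward_project(image$values, view_angles(geometry),
                              geometry$n_bins, geometry$bin_spacing,
                              geometry$pixel_size)
  sinogram(vals, geometry)
}

#' Analytic sinogram of a uniform disk
#'
#' Closed-form line integrals of a homogeneous disk: for a disk of radius
#' `r` and attenuation `mu` centered at `(cx, cy)`, the projection at view
#' angle `theta` is `2 * mu * sqrt(r^2 - (s - s0)^2)` for `|s - s0| < r`
#' and zero otherwise, where `s0 = cx * cos(theta) + cy * sin(theta)` is
#' the projected center. Exact (non-discretized); serves as the independent
#' ground truth that the numerical projector is tested against.
#'
#' @param center numeric length-2, physical `(x, y)` of the disk center.
#' @param radius disk radius in physical units (0 gives an all-zero
#'   sinogram).
#' @param attenuation disk attenuation value.
#' @param geometry a [scan_geometry()].
#' @return A [sinogram()].
#' @export
analytic_disk_sinogram <- function(center, radius, attenuation, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"),
            length(center) == 2, radius >= 0)
  fov_r <- geometry$image_size * geometry$pixel_size / 2
  if (sqrt(sum(center^2)) + radius > fov_r + 1e-9) {
    stop("disk (center distance ", round(sqrt(sum(center^2)), 3),
         ", radius ", radius, ") extends outside the field of view (radius ",
         fov_r, ")", call. = FALSE)
  }
  s <- detector_positions(geometry)
  th <- view_angles(geometry)
  s0 <- center[1] * cos(th) + center[2] * sin(th)   # projected disk center
  d2 <- outer(s, s0, function(si, ci) radius^2 - (si - ci)^2)
  vals <- 2 * attenuation * sqrt(pmax(d2, 0))
  sinogram(vals, geometry)
}

#' Analytic metal-trace support of a disk
#'
#' Boolean sinogram-domain support of a disk: bin `(k, v)` is inside the
#' trace when its ray passes through the disk, i.e. `|s_k - s0(theta_v)| <
#' radius`. Used as the geometric oracle for [compute_metal_trace()].
#'
#' @inheritParams analytic_disk_sinogram
#' @return logical matrix `n_bins x n_views`.
#' @export
analytic_disk_trace <- function(center, radius, geometry) {
  s <- detector_positions(geometry)
  th <- view_angles(geometry)
  s0 <- center[1] * cos(th) + center[2] * sin(th)
  outer(s, s0, function(si, ci) abs(si - ci) < radius)
}
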