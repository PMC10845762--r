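#' Filtered backprojection reconstruction
#'
#' The pipeline's reconstructor: each projection is filtered in the
#' frequency domain with a ramp-family filter (see [build_filter()]) and
#' smeared back across the image grid along its rays (pixel-driven
#' backprojection, linear interpolation in the detector coordinate; an
#' exact half-bin position resolves toward the lower index). For a full
#' 360-degree scan the backprojection sum is scaled by `angle_step / 2`
#' (in radians), so a consistent forward model reconstructs in the
#' original attenuation units.
#'
#' Negative reconstructed values are retained, not clipped.
#'
#' @param sino a [sinogram()] with all entries valid. Invalid entries
#'   (removed views, metal tracks) must be completed first — see
#'   [linear_interpolate()] / [unet_synthesize()].
#' @param config an [fbp_config()]; default shepp-logan filter with
#'   cutoff 1.0.
#' @return An [image_slice()] on the geometry's grid. Deterministic for a
#'   fixed input.
#' @examples
#' geom <- scan_geometry(image_size = 64, n_bins = 96)
#' disk <- analytic_disk_sinogram(c(0, 0), 20, 1, geom)
#' rec <- fbp_reconstruct(disk)
#' mean(rec$values[32:33, 32:33])   # close to the disk attenuation 1
#' @export
fbp_reconstruct <- function(sino, config = fbp_config()) {
  stopifnot(inherits(sino, "sinogram"), inherits(config, "fbp_config"))
  if (!all(sino$valid)) {
    stop("sinogram has ", sum(!sino$valid), " invalid entries; complete it ",
         "first (linear_interpolate / unet_synthesize) before FBP",
         call. = FALSE)
  }
  g <- sino$geometry
  q <- filter_projections(sino$values, config, g$bin_spacing)
  img <- cpp_pixel_backproject(q, view_angles(g), g$image_size,
                               g$bin_spacing, g$pixel_size)
  dtheta <- g$angle_step_deg * pi / 180
  # each parallel-beam direction is measured (coverage / 180 deg) times:
  # twice for a full 360-degree scan, once for a 180-degree half scan
  redundancy <- g$n_views * g$angle_step_deg / 180
  image_slice(img * dtheta / redundancy, g)
}

# Frequency-domain ramp filtering of all projections at once.
# Zero-pads to at least twice the detector length (next power of two) to
# suppress circular-convolution wrap-around.
filter_projections <- function(values, config, bin_spacing) {
  nb <- nrow(values)
  n_pad <- 2^ceiling(log2(2 * nb))
  h <- build_filter(config$filter_name, config$cutoff, n_pad, bin_spacing)
  padded <- rbind(values, matrix(0, n_pad - nb, ncol(values)))
  q <- Re(mvfft(mvfft(padded) * h, inverse = TRUE)) / n_pad
  q[seq_len(nb), , drop = FALSE]
}
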