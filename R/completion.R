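#' Decimate a sinogram in the angular direction
#'
#' Keeps every `factor`-th view starting from the first one (original view
#' indices 1, 1 + factor, 1 + 2 factor, ...) and scales the angular step
#' accordingly: decimating a 360-view, 1-degree scan by 4 yields the
#' 90-view, 4-degree sparse acquisition that emulates the reduced scan
#' time. Used by the simulation module.
#'
#' @param sino a [sinogram()].
#' @param factor positive integer dividing `n_views` exactly.
#' @return A [sinogram()] with `n_views / factor` views.
#' @export
downsample_views <- function(sino, factor) {
  stopifnot(inherits(sino, "sinogram"))
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  g <- sino$geometry
  if (g$n_views %% factor != 0) {
    stop("n_views (", g$n_views, ") is not divisible by factor (", factor,
         ")", call. = FALSE)
  }
  if (factor == 1) return(sino)
  keep <- seq(1, g$n_views, by = factor)
  g2 <- scan_geometry(n_views = g$n_views / factor,
                      angle_step_deg = g$angle_step_deg * factor,
                      n_bins = g$n_bins, bin_spacing = g$bin_spacing,
                      image_size = g$image_size, pixel_size = g$pixel_size)
  sinogram(sino$values[, keep, drop = FALSE], g2,
           sino$valid[, keep, drop = FALSE])
}

#' Up-sample the angular grid of a sinogram
#'
#' Expands a sparse sinogram onto a `factor`-times finer view grid: the
#' measured views are copied to their original angular positions (view `v`
#' goes to column `(v - 1) * factor + 1`) and keep their validity; the
#' `(factor - 1) * n_views` inserted views are flagged invalid, to be
#' filled by [linear_interpolate()] and [unet_synthesize()]. Up-sampling a
#' 90-view sinogram by 4 restores the 360-view grid.
#'
#' @param sino a [sinogram()].
#' @param factor integer >= 1.
#' @return A [sinogram()] with `n_views * factor` views.
#' @export
upsample_view_grid <- function(sino, factor) {
  stopifnot(inherits(sino, "sinogram"))
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(sino)
  g <- sino$geometry
  g2 <- scan_geometry(n_views = g$n_views * factor,
                      angle_step_deg = g$angle_step_deg / factor,
                      n_bins = g$n_bins, bin_spacing = g$bin_spacing,
                      image_size = g$image_size, pixel_size = g$pixel_size)
  vals <- matrix(0, g$n_bins, g2$n_views)
  valid <- matrix(FALSE, g$n_bins, g2$n_views)
  pos <- (seq_len(g$n_views) - 1) * factor + 1
  vals[, pos] <- sino$values
  valid[, pos] <- sino$valid
  sinogram(vals, g2, valid)
}

#' Linear-interpolation initialization of missing sinogram data
#'
#' Fills every invalid entry of a sinogram: bins invalid inside
#' otherwise-measured views (metal tracks) are filled first by linear
#' interpolation along the detector direction within each view (a gap is
#' bridged by the straight line between its flanking valid bins; a gap
#' touching the detector edge is extended with the nearest valid value);
#' then fully invalid views (removed by angular decimation) are filled by
#' linear interpolation along the angular direction between the flanking
#' measured views, with 360-degree wrap-around across the last-to-first
#' seam — views are periodic for a full-scan geometry. Measured entries
#' are never changed.
#'
#' @param sino a [sinogram()] with at least one (partially) valid view;
#'   each partially valid view must contain at least one valid bin.
#' @return A fully valid [sinogram()]; the attribute `"filled"` is a
#'   logical matrix marking the entries that were synthesized (the
#'   original invalid set), which [unet_synthesize()] uses as its
#'   write-back mask.
#' @export
linear_interpolate <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  vals <- sino$values
  valid <- sino$valid
  filled <- !valid
  if (!any(filled)) {
    out <- sinogram(vals, sino$geometry, matrix(TRUE, nrow(vals), ncol(vals)))
    attr(out, "filled") <- filled
    return(out)
  }
  view_has_data <- colSums(valid) > 0
  if (!any(view_has_data)) {
    stop("no valid data in any view: completion impossible", call. = FALSE)
  }
  # pass 1: detector-direction fill of gaps inside measured views
  for (v in which(view_has_data)) {
    miss <- !valid[, v]
    if (!any(miss)) next
    ok <- which(!miss)
    vals[miss, v] <- stats::approx(ok, vals[ok, v], xout = which(miss),
                                   rule = 2)$y
  }
  # pass 2: angular fill of fully missing views, periodic over 360 degrees
  miss_v <- which(!view_has_data)
  if (length(miss_v) > 0) {
    ok_v <- which(view_has_data)
    nv <- ncol(vals)
    # replicate the measured views one period before and after the scan so
    # stats::approx interpolates across the 360-degree seam
    xs <- c(ok_v - nv, ok_v, ok_v + nv)
    for (b in seq_len(nrow(vals))) {
      ys <- rep(vals[b, ok_v], 3)
      vals[b, miss_v] <- stats::approx(xs, ys, xout = miss_v)$y
    }
  }
  out <- sinogram(vals, sino$geometry, matrix(TRUE, nrow(vals), ncol(vals)))
  attr(out, "filled") <- filled
  out
}

#' Patch-based sinogram synthesis with the trained modified U-Net
#'
#' Runs the trained sinogram network over an initialized (fully valid)
#' sinogram: the sinogram is tiled into overlapping patches (default
#' stride: half the patch size), each patch is passed through the model,
#' overlapping predictions are blended by uniform averaging, and the
#' result overwrites only the originally invalid entries — measured bins
#' are restored verbatim, which guarantees data fidelity at the retained
#' samples. Deterministic given the model weights.
#'
#' @param sino a fully valid [sinogram()], normally the output of
#'   [linear_interpolate()].
#' @param model a trained `sinomar_net` of kind `modified_unet` (see
#'   [build_modified_unet()], [train_model()]).
#' @param fill logical matrix marking the entries to overwrite; defaults
#'   to the `"filled"` attribute left by [linear_interpolate()].
#' @param patch_size patch side in pixels; defaults to the model's
#'   configured patch size (64 for the sinogram network).
#' @param stride tiling stride; default `patch_size / 2`.
#' @return A fully valid [sinogram()] with the same `"filled"` attribute.
#' @export
unet_synthesize <- function(sino, model, fill = attr(sino, "filled"),
                            patch_size = NULL, stride = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  if (!inherits(model, "sinomar_net")) {
    stop("`model` must be a sinomar_net (see build_modified_unet / ",
         "train_model)", call. = FALSE)
  }
  if (!all(sino$valid)) {
    stop("sinogram must be initialized (fully valid) before synthesis; ",
         "run linear_interpolate first", call. = FALSE)
  }
  if (is.null(fill)) {
    stop("no fill mask: pass `fill` or use the output of linear_interpolate",
         call. = FALSE)
  }
  stopifnot(is.logical(fill), all(dim(fill) == dim(sino$values)))
  pred <- apply_model_tiled(sino$values, model, patch_size, stride)
  vals <- sino$values
  vals[fill] <- pred[fill]
  out <- sinogram(vals, sino$geometry)
  attr(out, "filled") <- fill
  out
}
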