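#' Root-mean-square error
#'
#' `sqrt(sum((test - reference)^2) / N)` over the evaluation region, with
#' `N` the number of pixels in the region (per-pixel differences).
#' Symmetric in its two arguments.
#'
#' @param test,reference numeric arrays of identical shape (matrices,
#'   [image_slice()]s or [sinogram()]s).
#' @param roi optional logical mask of the same shape selecting the region
#'   of interest; default: the full array.
#' @return non-negative scalar.
#' @export
rmse <- function(test, reference, roi = NULL) {
  test <- as_values(test)
  reference <- as_values(reference)
  if (!all(dim(test) == dim(reference))) {
    stop("test and reference shapes differ", call. = FALSE)
  }
  d <- test - reference
  if (!is.null(roi)) {
    stopifnot(is.logical(roi), all(dim(roi) == dim(test)))
    if (!any(roi)) stop("empty ROI", call. = FALSE)
    d <- d[roi]
  }
  sqrt(mean(d^2))
}

#' Peak signal-to-noise ratio, in dB
#'
#' `10 * log10(m_peak^2 / MSE)` where `m_peak` is the maximum intensity
#' over both images (not a fixed bit-depth range) and MSE the mean squared
#' error between them. Identical images have zero MSE and return `Inf`.
#'
#' @inheritParams rmse
#' @return scalar in dB (`Inf` for identical inputs).
#' @export
psnr <- function(test, reference, roi = NULL) {
  test <- as_values(test)
  reference <- as_values(reference)
  if (!all(dim(test) == dim(reference))) {
    stop("test and reference shapes differ", call. = FALSE)
  }
  m_peak <- max(test, reference)
  mse <- rmse(test, reference, roi)^2
  if (mse == 0) return(Inf)
  10 * log10(m_peak^2 / mse)
}

#' Structural similarity index (single-window)
#'
#' Global SSIM over the evaluation region:
#' `((2 m_ref m_test + c1) (2 cov + c2)) /
#'  ((m_ref^2 + m_test^2 + c1) (var_ref + var_test + c2))`
#' computed from the means, population variances and covariance of the two
#' arrays as a whole — a single window, not a sliding one. Two stabilizer
#' readings are available: in the default `"literal"` mode the constants
#' enter the formula directly as `c1 = k1`, `c2 = k2` (defaults `k1 =
#' 0.001`, `k2 = 0.03`); in `"scaled"` mode the conventional scaling `c1 =
#' (k1 L)^2`, `c2 = (k2 L)^2` is applied with `L` the reference dynamic
#' range. Symmetric in its arguments (both modes use the shared `L` of the
#' joint range in `"scaled"` mode... see Details).
#'
#' @details In `"scaled"` mode `L` is taken as the dynamic range of the
#'   reference image; swapping the arguments then changes `L`, so strict
#'   symmetry holds in `"literal"` mode only. The stabilizers also guard
#'   the constant-zero pair: no division by zero can occur for positive
#'   `k1`, `k2`.
#'
#' @inheritParams rmse
#' @param k1,k2 stabilizing constants (defaults 0.001 and 0.03).
#' @param mode `"literal"` (default) or `"scaled"`.
#' @return scalar in `[-1, 1]`; exactly 1 for identical arrays.
#' @export
ssim <- function(test, reference, k1 = 0.001, k2 = 0.03,
                 mode = c("literal", "scaled"), roi = NULL) {
  mode <- match.arg(mode)
  test <- as_values(test)
  reference <- as_values(reference)
  if (!all(dim(test) == dim(reference))) {
    stop("test and reference shapes differ", call. = FALSE)
  }
  if (!is.null(roi)) {
    stopifnot(is.logical(roi), all(dim(roi) == dim(test)))
    if (!any(roi)) stop("empty ROI", call. = FALSE)
    test <- test[roi]
    reference <- reference[roi]
  }
  n <- length(test)
  m_e <- mean(test)
  m_r <- mean(reference)
  v_e <- sum((test - m_e)^2) / n      # population variance
  v_r <- sum((reference - m_r)^2) / n
  cv <- sum((test - m_e) * (reference - m_r)) / n
  if (mode == "literal") {
    c1 <- k1
    c2 <- k2
  } else {
    L <- diff(range(reference))
    if (L == 0) L <- 1
    c1 <- (k1 * L)^2
    c2 <- (k2 * L)^2
  }
  ((2 * m_r * m_e + c1) * (2 * cv + c2)) /
    ((m_r^2 + m_e^2 + c1) * (v_r + v_e + c2))
}

#' Contrast-to-noise ratio between two regions
#'
#' `(m_x - m_ref) / sqrt(sigma_x^2 + sigma_ref^2)` with means and standard
#' deviations taken over the target and reference regions of one image
#' (for the simulated specimens: a fibroglandular region against the
#' adipose background). The sign is preserved — swapping the regions flips
#' it. If both regions are constant and equal, the 0/0 case returns 0 with
#' a warning.
#'
#' @param image numeric matrix or [image_slice()].
#' @param roi_target,roi_reference logical masks (same shape as the image)
#'   or index vectors; must be non-empty and disjoint.
#' @return scalar CNR.
#' @export
cnr <- function(image, roi_target, roi_reference) {
  vals <- as_values(image)
  pick <- function(roi, what) {
    if (is.logical(roi)) {
      stopifnot(all(dim(roi) == dim(vals)))
      idx <- which(roi)
    } else {
      idx <- as.integer(roi)
    }
    if (length(idx) == 0) stop(what, " ROI is empty", call. = FALSE)
    idx
  }
  it <- pick(roi_target, "target")
  ir <- pick(roi_reference, "reference")
  if (length(intersect(it, ir)) > 0) {
    stop("target and reference ROIs overlap", call. = FALSE)
  }
  num <- mean(vals[it]) - mean(vals[ir])
  den <- sqrt(pop_var(vals[it]) + pop_var(vals[ir]))
  if (den == 0) {
    if (num == 0) {
      warning("both ROIs constant and equal: CNR is 0/0, returning 0",
              call. = FALSE)
      return(0)
    }
    return(sign(num) * Inf)
  }
  num / den
}

pop_var <- function(x) sum((x - mean(x))^2) / length(x)

#' Rectangular region-of-interest mask
#'
#' @param dim integer length-2 array dimensions, or a matrix /
#'   [image_slice()] whose dimensions to use.
#' @param rows,cols integer ranges of the rectangle.
#' @return logical mask matrix.
#' @export
roi_rect <- function(dim, rows, cols) {
  if (!is.null(base::dim(as_values(dim)))) {
    dim <- base::dim(as_values(dim))
  }
  stopifnot(length(dim) == 2, min(rows) >= 1, max(rows) <= dim[1],
            min(cols) >= 1, max(cols) <= dim[2])
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  m
}

#' Intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at `n_samples` evenly
#' spaced positions between two endpoints, for the profile plots used to
#' compare reconstruction methods. With `n_samples = 2` the result is
#' exactly the two endpoint values.
#'
#' @param image numeric matrix or [image_slice()].
#' @param start,end numeric length-2 endpoints `(row, col)`, 1-based,
#'   inside the grid.
#' @param n_samples number of samples (>= 2).
#' @return data.frame with columns `position` (distance from `start`, in
#'   pixels) and `value`.
#' @export
line_profile <- function(image, start, end, n_samples = 100L) {
  vals <- as_values(image)
  stopifnot(length(start) == 2, length(end) == 2, n_samples >= 2)
  for (p in list(start, end)) {
    if (p[1] < 1 || p[1] > nrow(vals) || p[2] < 1 || p[2] > ncol(vals)) {
      stop("profile endpoint (", p[1], ", ", p[2],
           ") lies outside the image grid", call. = FALSE)
    }
  }
  t <- seq(0, 1, length.out = n_samples)
  rows <- start[1] + t * (end[1] - start[1])
  cols <- start[2] + t * (end[2] - start[2])
  data.frame(position = t * sqrt(sum((end - start)^2)),
             value = cpp_bilinear_sample(vals, rows, cols))
}

#' Assemble a per-method metric report row
#'
#' @param method method label.
#' @param image reconstructed image (matrix or [image_slice()]).
#' @param reference ground-truth image.
#' @param roi_target,roi_reference CNR regions (see [cnr()]); if `NULL`,
#'   CNR is reported as `NA`.
#' @param roi optional evaluation mask for SSIM/PSNR/RMSE.
#' @return one-row data.frame with columns `method`, `ssim`, `cnr`,
#'   `psnr`, `rmse`.
#' @export
metric_report <- function(method, image, reference, roi_target = NULL,
                          roi_reference = NULL, roi = NULL) {
  data.frame(
    method = method,
    ssim = ssim(image, reference, roi = roi),
    cnr = if (is.null(roi_target)) NA_real_ else
      cnr(image, roi_target, roi_reference),
    psnr = psnr(image, reference, roi = roi),
    rmse = rmse(image, reference, roi = roi))
}
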