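#' FBP reconstruction filter configuration
#'
#' @param filter_name `"shepp-logan"` (default, the ramp apodized by a sinc
#'   window) or `"ram-lak"` (the pure ramp).
#' @param cutoff relative cutoff frequency in `(0, 1]`, as a fraction of
#'   the detector Nyquist frequency; the response is zero above it.
#'   Default 1.0.
#' @return An object of class `fbp_config`.
#' @export
fbp_config <- function(filter_name = c("shepp-logan", "ram-lak"),
                       cutoff = 1.0) {
  filter_name <- match.arg(filter_name)
  if (!is.numeric(cutoff) || length(cutoff) != 1 ||
      cutoff <= 0 || cutoff > 1) {
    stop("cutoff must lie in (0, 1], got ", cutoff, call. = FALSE)
  }
  structure(list(filter_name = filter_name, cutoff = cutoff),
            class = "fbp_config")
}

#' Frequency response of an FBP ramp-family filter
#'
#' Builds the discrete frequency response used by [fbp_reconstruct()]:
#' `|f|` for the ram-lak filter, `|f| * sinc(f / (2 * cutoff * f_N))` for
#' shepp-logan (so the sinc window closes exactly at the cutoff), and zero
#' above `cutoff * f_N`, where `f_N` is the detector Nyquist frequency.
#' Frequencies follow the unshifted DFT layout of an `n`-point transform.
#'
#' @param filter_name `"ram-lak"` or `"shepp-logan"`.
#' @param cutoff relative cutoff in `(0, 1]`.
#' @param n_bins transform length (>= 2).
#' @param bin_spacing detector sampling interval (sets the frequency unit).
#' @return numeric vector of length `n_bins`: real, non-negative response,
#'   zero at DC and above the cutoff.
#' @export
build_filter <- function(filter_name = c("shepp-logan", "ram-lak"),
                         cutoff = 1.0, n_bins = 256, bin_spacing = 1) {
  filter_name <- match.arg(filter_name)
  if (cutoff <= 0 || cutoff > 1) {
    stop("cutoff must lie in (0, 1], got ", cutoff, call. = FALSE)
  }
  stopifnot(n_bins >= 2)
  # unshifted DFT frequencies in cycles per unit detector length
  k <- seq_len(n_bins) - 1
  k <- ifelse(k > n_bins / 2, k - n_bins, k)
  f <- k / (n_bins * bin_spacing)
  f_nyq <- 1 / (2 * bin_spacing)
  h <- abs(f)
  if (filter_name == "shepp-logan") {
    # sinc window that reaches zero at the cutoff frequency
    arg <- f / (2 * cutoff * f_nyq)
    w <- ifelse(arg == 0, 1, sin(pi * arg) / (pi * arg))
    h <- h * pmax(w, 0)
  }
  h[abs(f) > cutoff * f_nyq + 1e-12] <- 0
  h
}
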