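#' Image-domain denoising with the trained modified ResU-Net
#'
#' Applies the trained image network to a reconstructed slice: the image
#' is tiled into overlapping patches (default 48 px, stride half the patch
#' size), each patch is denoised by the model, and overlapping predictions
#' are blended by uniform averaging. Deterministic given the model
#' weights. This stage handles the residual streaks left after sinogram
#' completion and FBP; metal reinsertion happens afterwards.
#'
#' @param image an [image_slice()].
#' @param model a trained `sinomar_net` of kind `modified_resunet`.
#' @param patch_size,stride tiling parameters; defaults: the model's patch
#'   size and half of it.
#' @return An [image_slice()].
#' @export
resunet_denoise <- function(image, model, patch_size = NULL, stride = NULL) {
  stopifnot(inherits(image, "image_slice"))
  if (!inherits(model, "sinomar_net")) {
    stop("`model` must be a sinomar_net (see build_modified_resunet / ",
         "train_model)", call. = FALSE)
  }
  vals <- apply_model_tiled(image$values, model, patch_size, stride)
  image_slice(vals, image$geometry)
}
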