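#' End-to-end pipeline configuration
#'
#' Bundles everything the reconstruction strategies need: the dense-scan
#' geometry, the angular up-sampling factor, the metal segmentation
#' threshold, the trained models and the reconstruction configs.
#'
#' @param geometry the dense (fully sampled) [scan_geometry()] the sparse
#'   scan is up-sampled to.
#' @param upsample_factor angular up-sampling factor (default 4: 90 to
#'   360 views).
#' @param metal_threshold image-domain segmentation threshold; the default
#'   25.1 is the midpoint between the simulation's metal attenuation (50)
#'   and its maximum soft-tissue attenuation (about 0.45 with texture),
#'   rounded up, guaranteeing exact segmentation on synthetic data.
#' @param sino_model trained `modified_unet` for sinogram synthesis, or
#'   `NULL` for methods that do not use it.
#' @param image_model trained `modified_resunet` for image denoising, or
#'   `NULL`.
#' @param fbp an [fbp_config()].
#' @param ir an [ir_config()] (used by the `"ir"` baseline).
#' @param metal_handling apply metal removal/reinsertion in the completion
#'   methods (default `TRUE`); set `FALSE` to reproduce naive
#'   reconstructions with full metal artifacts.
#' @param trace_dilate detector-direction dilation of the metal trace.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = scan_geometry(), upsample_factor = 4L,
                            metal_threshold = 25.1, sino_model = NULL,
                            image_model = NULL, fbp = fbp_config(),
                            ir = ir_config(), metal_handling = TRUE,
                            trace_dilate = 1L) {
  stopifnot(inherits(geometry, "scan_geometry"), upsample_factor >= 1)
  structure(list(geometry = geometry,
                 upsample_factor = as.integer(upsample_factor),
                 metal_threshold = metal_threshold,
                 sino_model = sino_model, image_model = image_model,
                 fbp = fbp, ir = ir,
                 metal_handling = isTRUE(metal_handling),
                 trace_dilate = as.integer(trace_dilate)),
            class = "pipeline_config")
}

# Shared front end of all completion-based methods: initial FBP of the
# sparse scan, metal segmentation and trace computation, angular
# up-sampling, metal removal, linear-interpolation initialization.
# Returns the initialized sinogram plus the metal mask for reinsertion.
completion_front_end <- function(sparse_sino, config) {
  init_fbp <- fbp_reconstruct(sparse_sino, config$fbp)
  mask <- NULL
  up <- upsample_view_grid(sparse_sino, config$upsample_factor)
  if (config$metal_handling) {
    mask <- segment_metal(init_fbp, config$metal_threshold)
    if (any(mask$support)) {
      trace <- compute_metal_trace(mask, up$geometry,
                                   dilate = config$trace_dilate)
      up <- remove_metal(up, trace)
    } else {
      mask <- NULL
    }
  }
  list(sino = linear_interpolate(up), mask = mask)
}

maybe_reinsert <- function(image, mask) {
  if (is.null(mask)) image else reinsert_metal(image, mask)
}

#' Run the proposed two-stage reconstruction
#'
#' Executes the full artifact-reduction chain on a sparse-view sinogram
#' with (possibly) embedded metal: initial FBP, metal segmentation by
#' thresholding, metal-trace removal after angular up-sampling,
#' linear-interpolation initialization, patch-based synthesis by the
#' trained modified U-Net, FBP of the completed sinogram, residual
#' denoising by the trained modified ResU-Net, and reinsertion of the
#' segmented metal. Deterministic given the model weights.
#'
#' @param sparse_sino the measured sparse-view [sinogram()].
#' @param config a [pipeline_config()] with both trained models set.
#' @param keep_intermediates if `TRUE`, attach a list of the named
#'   intermediate stages as attribute `"stages"`.
#' @return The final [image_slice()].
#' @export
run_proposed <- function(sparse_sino, config, keep_intermediates = FALSE) {
  stopifnot(inherits(sparse_sino, "sinogram"),
            inherits(config, "pipeline_config"))
  if (is.null(config$sino_model)) {
    stop("proposed pipeline needs a trained sinogram model ",
         "(config$sino_model) for the synthesis stage", call. = FALSE)
  }
  if (is.null(config$image_model)) {
    stop("proposed pipeline needs a trained image model ",
         "(config$image_model) for the denoising stage", call. = FALSE)
  }
  fe <- completion_front_end(sparse_sino, config)
  synth <- unet_synthesize(fe$sino, config$sino_model)
  recon <- fbp_reconstruct(synth, config$fbp)
  denoised <- resunet_denoise(recon, config$image_model)
  out <- maybe_reinsert(denoised, fe$mask)
  if (keep_intermediates) {
    attr(out, "stages") <- list(initialized = fe$sino, synthesized = synth,
                                fbp = recon, denoised = denoised,
                                metal_mask = fe$mask)
  }
  out
}

#' Run one comparison baseline
#'
#' The five reference strategies the proposed method is compared against:
#' `"fbp"` — plain FBP of the sparse sinogram; `"ir"` — penalized
#' weighted-least-squares reconstruction of the sparse sinogram;
#' `"lininterp"` — FBP of the linear-interpolation-completed sinogram;
#' `"image_denoise_only"` — lininterp followed by ResU-Net denoising (no
#' sinogram network); `"sino_unet_only"` — U-Net sinogram synthesis plus
#' FBP (no image network). The completion-based methods apply metal
#' removal and reinsertion identically (when `config$metal_handling` is
#' on), so the comparison isolates the learned stages; `"fbp"` and `"ir"`
#' reconstruct the raw sparse data with whatever artifacts it carries.
#'
#' @param sparse_sino the measured sparse-view [sinogram()].
#' @param method one of `"fbp"`, `"ir"`, `"lininterp"`,
#'   `"image_denoise_only"`, `"sino_unet_only"`, `"proposed"`.
#' @param config a [pipeline_config()].
#' @return An [image_slice()].
#' @export
run_baseline <- function(sparse_sino,
                         method = c("fbp", "ir", "lininterp",
                                    "image_denoise_only", "sino_unet_only",
                                    "proposed"),
                         config) {
  method <- match.arg(method)
  stopifnot(inherits(sparse_sino, "sinogram"),
            inherits(config, "pipeline_config"))
  switch(method,
    fbp = fbp_reconstruct(sparse_sino, config$fbp),
    ir = pwls_reconstruct(sparse_sino, config$ir),
    lininterp = {
      fe <- completion_front_end(sparse_sino, config)
      maybe_reinsert(fbp_reconstruct(fe$sino, config$fbp), fe$mask)
    },
    image_denoise_only = {
      if (is.null(config$image_model)) {
        stop("method 'image_denoise_only' needs config$image_model",
             call. = FALSE)
      }
      fe <- completion_front_end(sparse_sino, config)
      img <- fbp_reconstruct(fe$sino, config$fbp)
      maybe_reinsert(resunet_denoise(img, config$image_model), fe$mask)
    },
    sino_unet_only = {
      if (is.null(config$sino_model)) {
        stop("method 'sino_unet_only' needs config$sino_model",
             call. = FALSE)
      }
      fe <- completion_front_end(sparse_sino, config)
      synth <- unet_synthesize(fe$sino, config$sino_model)
      maybe_reinsert(fbp_reconstruct(synth, config$fbp), fe$mask)
    },
    proposed = run_proposed(sparse_sino, config))
}

#' Build sinogram-domain training pairs from simulated cases
#'
#' For each simulated case, runs the completion front end (initial FBP,
#' metal segmentation and removal, angular up-sampling,
#' linear-interpolation initialization) on the sparse sinogram and pairs
#' the initialized sinogram with the dense metal-free ground-truth
#' sinogram — the input/target layout the sinogram network is trained on.
#'
#' @param cases list of `sim_pair` objects (see [generate_dataset()]).
#' @param config a [pipeline_config()].
#' @return list with elements `inputs` and `targets` (lists of matrices),
#'   ready for [extract_patches()].
#' @export
sino_training_pairs <- function(cases, config) {
  inputs <- lapply(cases, function(cs) {
    completion_front_end(cs$sparse_sino, config)$sino$values
  })
  targets <- lapply(cases, function(cs) cs$gt_sino$values)
  list(inputs = inputs, targets = targets)
}

#' Build image-domain training pairs from simulated cases
#'
#' For each case, completes the sparse sinogram with the trained sinogram
#' network (falling back to linear interpolation when `sino_model` is
#' `NULL`), reconstructs it by FBP, and pairs the result with the
#' metal-free ground-truth image — the input/target layout the image
#' denoising network is trained on. Metal is absent from both sides: the
#' track was removed upstream and is reinserted only after denoising.
#'
#' @inheritParams sino_training_pairs
#' @param sino_model trained `modified_unet`, or `NULL` to pair against
#'   plain linear-interpolation reconstructions.
#' @return list with elements `inputs` and `targets` (lists of matrices).
#' @export
image_training_pairs <- function(cases, config, sino_model = NULL) {
  inputs <- lapply(cases, function(cs) {
    fe <- completion_front_end(cs$sparse_sino, config)
    sino <- if (is.null(sino_model)) fe$sino else
      unet_synthesize(fe$sino, sino_model)
    fbp_reconstruct(sino, config$fbp)$values
  })
  targets <- lapply(cases, function(cs) cs$gt_image$values)
  list(inputs = inputs, targets = targets)
}

#' Six-way method comparison on one case
#'
#' Reconstructs a sparse-view sinogram with all six strategies and
#' evaluates each against the reference image, producing one
#' [metric_report()] row per method (SSIM, CNR, PSNR, RMSE).
#'
#' @param sparse_sino the measured sparse-view [sinogram()].
#' @param reference ground-truth [image_slice()] to evaluate against
#'   (for simulated cases: the metal-embedded artifact-free image).
#' @param config a [pipeline_config()] with both models set.
#' @param roi_target,roi_reference CNR regions forwarded to [cnr()].
#' @param methods methods to include (default: all six).
#' @return data.frame with one row per method.
#' @export
compare_methods <- function(sparse_sino, reference, config,
                            roi_target = NULL, roi_reference = NULL,
                            methods = c("fbp", "ir", "lininterp",
                                        "image_denoise_only",
                                        "sino_unet_only", "proposed")) {
  rows <- lapply(methods, function(m) {
    img <- run_baseline(sparse_sino, m, config)
    metric_report(m, img, reference, roi_target, roi_reference)
  })
  do.call(rbind, rows)
}
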