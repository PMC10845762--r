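#' Sample a random two-class phantom specification
#'
#' Draws a randomized specimen phantom: an adipose-like background ellipse
#' (attenuation about 0.2) filling most of the field of view, and 3-7
#' fibroglandular-like ellipses (attenuation about 0.4) placed inside it.
#' All sizes scale with the geometry's field of view. Reproducible under a
#' fixed seed; distinct seeds give distinct anatomy.
#'
#' @param geometry a [scan_geometry()].
#' @param seed integer seed.
#' @param adipose_value,fibro_value class attenuations (defaults 0.2, 0.4).
#' @param noise_amplitude texture-noise amplitude forwarded to
#'   [phantom_spec()] (default 0.01).
#' @return A [phantom_spec()].
#' @export
sample_phantom_spec <- function(geometry, seed = 1L, adipose_value = 0.2,
                                fibro_value = 0.4, noise_amplitude = 0.01) {
  fov_r <- geometry$image_size * geometry$pixel_size / 2
  withr_seed(seed, {
    bg_axes <- runif(2, 0.70, 0.90) * fov_r
    bg <- list(center = c(0, 0), axes = bg_axes,
               angle_deg = runif(1, 0, 180), value = adipose_value)
    k <- sample(3:7, 1)
    tissues <- vector("list", k)
    for (i in seq_len(k)) {
      axes <- runif(2, 0.06, 0.22) * fov_r
      margin <- min(bg_axes) - max(axes) - 2 * geometry$pixel_size
      rr <- sqrt(runif(1)) * max(margin, 0)
      th <- runif(1, 0, 2 * pi)
      tissues[[i]] <- list(center = rr * c(cos(th), sin(th)), axes = axes,
                           angle_deg = runif(1, 0, 180),
                           value = fibro_value * runif(1, 0.9, 1.1))
    }
  })
  phantom_spec(bg, tissues, noise_amplitude = noise_amplitude,
               seed = seed + 7919L)
}

#' Simulate one paired artifact/ground-truth case
#'
#' Runs the full data-simulation chain that produces one training or
#' testing case: rasterize the metal-free ground-truth phantom, forward
#' project it at every view to get the dense ground-truth sinogram, embed
#' the metal wire (if any) and forward project again, decimate the views
#' (default by 4: 360 to 90) to emulate the reduced scan time, and
#' reconstruct the decimated metal sinogram by FBP to obtain the
#' streak-and-metal artifact image. Beam hardening is not simulated.
#' Optional Gaussian noise on the line integrals is off by default.
#'
#' @param spec a [phantom_spec()].
#' @param wire a [metal_wire_spec()] or `NULL` for a metal-free case.
#' @param geometry full-sampling [scan_geometry()] (the dense view grid).
#' @param decimation_factor integer dividing `n_views` (default 4).
#' @param noise_sd standard deviation of additive Gaussian noise applied
#'   to the line integrals (default 0 = noise-free).
#' @param fbp an [fbp_config()] for the artifact reconstruction.
#' @return An object of class `sim_pair`: `gt_image`, `gt_sino` (dense,
#'   metal-free), `metal_image`, `metal_mask`, `metal_trace` (`NULL` when
#'   no wire), `dense_sino` (with metal), `sparse_sino`, `artifact_image`
#'   (FBP of the sparse metal sinogram), plus the specs, factor and seed.
#' @export
simulate_pair <- function(spec, wire = NULL, geometry = scan_geometry(),
                          decimation_factor = 4L, noise_sd = 0,
                          fbp = fbp_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  gt_image <- generate_phantom(spec, geometry)
  gt_sino <- forward_project(gt_image)
  if (!is.null(wire)) {
    emb <- embed_metal(gt_image, wire)
    metal_image <- emb$image
    metal_mask <- emb$mask
    metal_trace <- compute_metal_trace(metal_mask, geometry)
    dense_sino <- forward_project(metal_image)
  } else {
    metal_image <- gt_image
    metal_mask <- NULL
    metal_trace <- NULL
    dense_sino <- gt_sino
  }
  if (noise_sd > 0) {
    withr_seed(spec$seed + 13L, {
      dense_sino$values <- dense_sino$values +
        matrix(rnorm(length(dense_sino$values), sd = noise_sd),
               nrow(dense_sino$values))
    })
  }
  sparse_sino <- downsample_views(dense_sino, decimation_factor)
  artifact_image <- fbp_reconstruct(sparse_sino, fbp)
  structure(list(gt_image = gt_image, gt_sino = gt_sino,
                 metal_image = metal_image, metal_mask = metal_mask,
                 metal_trace = metal_trace, dense_sino = dense_sino,
                 sparse_sino = sparse_sino, artifact_image = artifact_image,
                 spec = spec, wire = wire,
                 decimation_factor = as.integer(decimation_factor),
                 noise_sd = noise_sd, seed = spec$seed),
            class = "sim_pair")
}

#' Generate a dataset of simulated cases
#'
#' Draws `n_cases` phantoms with consecutive per-case seeds derived from
#' `seed`, simulates each with [simulate_pair()], and optionally writes
#' the whole dataset (arrays as multi-page TIFF, manifest as YAML) to a
#' directory via [write_dataset()]. The default desk-scale study uses 8
#' training and 2 held-out testing cases at 128 x 128.
#'
#' @param n_cases number of cases (>= 1).
#' @param geometry dense-scan [scan_geometry()].
#' @param seed base seed; case `i` uses `seed + 101 * i`.
#' @param wire a [metal_wire_spec()], `NULL` (no metal), or a function
#'   `function(case_seed)` returning one of those per case.
#' @param spec_sampler function `(geometry, seed)` returning a
#'   [phantom_spec()]; default [sample_phantom_spec()].
#' @param decimation_factor view decimation (default 4).
#' @param noise_sd line-integral noise (default 0).
#' @param out_path optional directory to write the dataset to.
#' @return list of `sim_pair` objects with attribute `"manifest"` (per-case
#'   seeds and settings); byte-identical manifests for identical seeds.
#' @export
generate_dataset <- function(n_cases, geometry = scan_geometry(), seed = 1L,
                             wire = NULL,
                             spec_sampler = sample_phantom_spec,
                             decimation_factor = 4L, noise_sd = 0,
                             out_path = NULL) {
  stopifnot(n_cases >= 1)
  cases <- vector("list", n_cases)
  manifest <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case_seed <- as.integer(seed + 101L * i)
    w <- if (is.function(wire)) wire(case_seed) else wire
    spec <- spec_sampler(geometry, case_seed)
    cases[[i]] <- simulate_pair(spec, w, geometry, decimation_factor,
                                noise_sd)
    manifest[[i]] <- list(case = i, seed = case_seed,
                          has_metal = !is.null(w),
                          decimation_factor = as.integer(decimation_factor),
                          noise_sd = noise_sd)
  }
  attr(cases, "manifest") <- manifest
  if (!is.null(out_path)) write_dataset(cases, out_path, seed)
  cases
}
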