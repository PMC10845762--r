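# Array I/O. Images and sinograms travel as 32-bit TIFF with a YAML
# sidecar (<path>.yaml) carrying the geometry, the intensity scaling used
# to map the data into the TIFF's [0, 1] sample range, and the object
# kind. A sinogram's validity mask is stored as a second TIFF page.

tiff_pages <- function(values_list, path) {
  tiff::writeTIFF(values_list, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
}

scale01 <- function(v) {
  lo <- min(v)
  hi <- max(v)
  s <- if (hi > lo) hi - lo else 1
  list(values = (v - lo) / s, lo = lo, hi = hi)
}

geometry_to_list <- function(g) {
  list(n_views = g$n_views, angle_step_deg = g$angle_step_deg,
       n_bins = g$n_bins, bin_spacing = g$bin_spacing,
       image_size = g$image_size, pixel_size = g$pixel_size)
}

geometry_from_list <- function(l) {
  scan_geometry(n_views = l$n_views, angle_step_deg = l$angle_step_deg,
                n_bins = l$n_bins, bin_spacing = l$bin_spacing,
                image_size = l$image_size, pixel_size = l$pixel_size,
                full_scan = FALSE)
}

#' Write a sinogram or image slice to TIFF
#'
#' The array is linearly mapped onto the 32-bit TIFF sample range and the
#' mapping, the geometry and (for sinograms) the validity mask are stored
#' alongside — the mask as a second TIFF page, the metadata in a
#' `<path>.yaml` sidecar. [read_ct_tiff()] restores the object.
#'
#' @param x a [sinogram()] or [image_slice()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_ct_tiff <- function(x, path) {
  if (inherits(x, "sinogram")) {
    sc <- scale01(x$values)
    tiff_pages(list(sc$values, x$valid * 1), path)
    meta <- list(kind = "sinogram", lo = sc$lo, hi = sc$hi,
                 geometry = geometry_to_list(x$geometry))
  } else if (inherits(x, "image_slice")) {
    sc <- scale01(x$values)
    tiff_pages(list(sc$values), path)
    meta <- list(kind = "image_slice", lo = sc$lo, hi = sc$hi,
                 geometry = geometry_to_list(x$geometry))
  } else {
    stop("x must be a sinogram or image_slice", call. = FALSE)
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a sinogram or image slice written by [write_ct_tiff()]
#'
#' @param path `.tif` path with its `.yaml` sidecar.
#' @return A [sinogram()] or [image_slice()], as written.
#' @export
read_ct_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  g <- geometry_from_list(meta$geometry)
  vals <- pages[[1]] * (meta$hi - meta$lo) + meta$lo
  if (meta$hi == meta$lo) vals <- pages[[1]] * 0 + meta$lo
  if (meta$kind == "sinogram") {
    valid <- if (length(pages) > 1) pages[[2]] > 0.5 else NULL
    sinogram(vals, g, valid)
  } else {
    image_slice(vals, g)
  }
}

#' Write a simulated dataset to a directory
#'
#' One subdirectory per case (`case_001`, ...) holding the ground-truth
#' image, the dense and sparse sinograms, the artifact FBP image and (for
#' metal cases) the metal mask, plus a `manifest.yaml` recording the
#' per-case seeds and settings. Reproducible: the manifest is
#' byte-identical for identical seeds.
#'
#' @param cases list of `sim_pair` objects (see [generate_dataset()]).
#' @param path output directory (created if needed).
#' @param seed the base seed that produced the dataset (recorded in the
#'   manifest).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cases, path, seed = NULL) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    stop("cannot create dataset directory ", path, call. = FALSE)
  }
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    d <- file.path(path, sprintf("case_%03d", i))
    dir.create(d, showWarnings = FALSE)
    write_ct_tiff(cs$gt_image, file.path(d, "gt_image.tif"))
    write_ct_tiff(cs$gt_sino, file.path(d, "gt_sino.tif"))
    write_ct_tiff(cs$metal_image, file.path(d, "metal_image.tif"))
    write_ct_tiff(cs$dense_sino, file.path(d, "dense_sino.tif"))
    write_ct_tiff(cs$sparse_sino, file.path(d, "sparse_sino.tif"))
    write_ct_tiff(cs$artifact_image, file.path(d, "artifact_image.tif"))
    if (!is.null(cs$metal_mask)) {
      mm <- image_slice(ifelse(cs$metal_mask$support,
                               cs$metal_mask$metal_values, 0),
                        cs$gt_image$geometry)
      write_ct_tiff(mm, file.path(d, "metal_values.tif"))
    }
  }
  manifest <- attr(cases, "manifest")
  yaml::write_yaml(list(n_cases = length(cases), seed = seed,
                        cases = manifest),
                   file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path dataset directory.
#' @return list of cases; each holds the stored arrays (metal masks are
#'   rebuilt from the stored metal-value image). The manifest is attached
#'   as attribute `"manifest"`.
#' @export
read_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.yaml")
  if (!file.exists(mf_path)) {
    stop("not a dataset directory (no manifest.yaml): ", path,
         call. = FALSE)
  }
  mf <- yaml::read_yaml(mf_path)
  cases <- vector("list", mf$n_cases)
  for (i in seq_len(mf$n_cases)) {
    d <- file.path(path, sprintf("case_%03d", i))
    cs <- list(gt_image = read_ct_tiff(file.path(d, "gt_image.tif")),
               gt_sino = read_ct_tiff(file.path(d, "gt_sino.tif")),
               metal_image = read_ct_tiff(file.path(d, "metal_image.tif")),
               dense_sino = read_ct_tiff(file.path(d, "dense_sino.tif")),
               sparse_sino = read_ct_tiff(file.path(d, "sparse_sino.tif")),
               artifact_image = read_ct_tiff(file.path(d,
                                                       "artifact_image.tif")))
    mv_path <- file.path(d, "metal_values.tif")
    if (file.exists(mv_path)) {
      mv <- read_ct_tiff(mv_path)
      supp <- mv$values > 0
      vals <- matrix(NA_real_, nrow(supp), ncol(supp))
      vals[supp] <- mv$values[supp]
      cs$metal_mask <- structure(list(support = supp, metal_values = vals,
                                      geometry = mv$geometry),
                                 class = "metal_mask")
    }
    cases[[i]] <- cs
  }
  attr(cases, "manifest") <- mf$cases
  cases
}

#' Save / load a trained network
#'
#' Thin RDS wrappers kept as named entry points so weight files are
#' written and checked consistently.
#'
#' @param model a `sinomar_net`.
#' @param path weights file path.
#' @return `save_model`: `path`, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sinomar_net"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  m <- readRDS(path)
  if (!inherits(m, "sinomar_net")) {
    stop(path, " does not contain a sinomar_net", call. = FALSE)
  }
  m
}
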