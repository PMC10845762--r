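#' Soft-tissue phantom specification
#'
#' Describes a piecewise-constant two-class specimen phantom: a background
#' ellipse standing in for the adipose bulk of a resected breast specimen,
#' plus a list of denser ellipses mimicking fibroglandular structure.
#' Later structures overwrite earlier ones. Metal is never part of the
#' phantom spec; it is added separately by [embed_metal()] so the
#' metal-free ground truth stays available.
#'
#' @param background list with `center` (physical `(x, y)`), `axes`
#'   (semi-axes), `angle_deg` and `value` (attenuation, >= 0).
#' @param tissues list of ellipse lists in the same format.
#' @param noise_amplitude standard deviation of seeded Gaussian texture
#'   noise added inside the phantom support (default 0.01; 0 disables).
#' @param seed integer seed for the texture noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(background, tissues = list(),
                         noise_amplitude = 0.01, seed = 1L) {
  check_ellipse <- function(e, what) {
    if (!all(c("center", "axes", "value") %in% names(e))) {
      stop(what, " needs fields center, axes, value", call. = FALSE)
    }
    if (e$value < 0) stop(what, " attenuation must be non-negative",
                          call. = FALSE)
    e$angle_deg <- e$angle_deg %||% 0
    e
  }
  background <- check_ellipse(background, "background ellipse")
  tissues <- lapply(seq_along(tissues), function(i) {
    check_ellipse(tissues[[i]], paste0("tissue ellipse ", i))
  })
  stopifnot(noise_amplitude >= 0)
  structure(list(background = background, tissues = tissues,
                 noise_amplitude = noise_amplitude, seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical coordinates of pixel centers (x along columns, y along rows)
grid_coords <- function(geometry, supersample = 1L) {
  n <- geometry$image_size * supersample
  px <- geometry$pixel_size / supersample
  x <- (seq_len(n) - (n + 1) / 2) * px
  list(x = x, y = rev(x), n = n)
}

# subpixel coverage fraction of an ellipse, block-averaged to the grid
ellipse_coverage <- function(e, geometry, supersample = 4L) {
  g <- grid_coords(geometry, supersample)
  phi <- e$angle_deg * pi / 180
  dx <- outer(rep(1, g$n), g$x - e$center[1])
  dy <- outer(g$y - e$center[2], rep(1, g$n))
  u <- (dx * cos(phi) + dy * sin(phi)) / e$axes[1]
  v <- (-dx * sin(phi) + dy * cos(phi)) / e$axes[2]
  fine <- (u^2 + v^2) <= 1
  n <- geometry$image_size
  ss <- supersample
  # block mean over ss x ss subpixels
  m <- matrix(colMeans(matrix(fine, ss)), n, n * ss)    # average row blocks
  t(matrix(colMeans(matrix(t(m), ss)), n, n))           # average col blocks
}

#' Rasterize a phantom onto the reconstruction grid
#'
#' Renders the spec's ellipses in order (background first, then tissue
#' structures, later ones overwriting earlier ones) with anti-aliased
#' edges: each pixel's value is blended by the ellipse's subpixel coverage
#' fraction (4x4 supersampling). Seeded Gaussian texture noise is then
#' added inside the phantom support and the result is clamped at zero.
#' Deterministic under a fixed spec seed.
#'
#' @param spec a [phantom_spec()].
#' @param geometry a [scan_geometry()].
#' @param supersample anti-aliasing factor (default 4).
#' @return An [image_slice()]; non-negative everywhere.
#' @export
generate_phantom <- function(spec, geometry, supersample = 4L) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(geometry, "scan_geometry"))
  fov_r <- geometry$image_size * geometry$pixel_size / 2
  for (e in c(list(spec$background), spec$tissues)) {
    if (sqrt(sum(e$center^2)) + max(e$axes) > fov_r + 1e-9) {
      stop("ellipse (value ", e$value, ") extends outside the field of ",
           "view (radius ", fov_r, ")", call. = FALSE)
    }
  }
  n <- geometry$image_size
  vals <- matrix(0, n, n)
  support <- matrix(FALSE, n, n)
  for (e in c(list(spec$background), spec$tissues)) {
    cov <- ellipse_coverage(e, geometry, supersample)
    vals <- vals * (1 - cov) + e$value * cov
    support <- support | (cov > 0)
  }
  if (spec$noise_amplitude > 0) {
    withr_seed(spec$seed, {
      noise <- matrix(rnorm(n * n, sd = spec$noise_amplitude), n, n)
    })
    vals[support] <- vals[support] + noise[support]
    vals <- pmax(vals, 0)
  }
  image_slice(vals, geometry)
}

#' Metal wire specification
#'
#' Describes the metallic needle marker embedded into a phantom: either a
#' disk (the wire seen end-on) or a line-segment capsule (seen side-on).
#' Its attenuation must exceed everything in the tissue phantom, which is
#' what makes threshold segmentation exact on simulated data.
#'
#' @param shape `"disk"` or `"capsule"`.
#' @param center physical `(x, y)` of the wire center.
#' @param radius disk radius, or capsule half-width, in physical units
#'   (pixels at the default `pixel_size = 1`).
#' @param length capsule segment length (ignored for disks).
#' @param angle_deg capsule orientation.
#' @param attenuation wire attenuation; must be much larger than tissue
#'   (default 50 against tissue values of about 0.2-0.4).
#' @return An object of class `metal_wire_spec`.
#' @export
metal_wire_spec <- function(shape = c("disk", "capsule"), center = c(0, 0),
                            radius = 3, length = 0, angle_deg = 0,
                            attenuation = 50) {
  shape <- match.arg(shape)
  stopifnot(radius >= 0, length >= 0, attenuation > 0)
  structure(list(shape = shape, center = center, radius = radius,
                 length = length, angle_deg = angle_deg,
                 attenuation = attenuation),
            class = "metal_wire_spec")
}

#' Embed a metal wire into a phantom image
#'
#' Sets every pixel whose center lies strictly inside the wire to the wire
#' attenuation (binary rasterization — the mask is exact, with no partial
#' pixels, so threshold segmentation can recover it perfectly) and returns
#' both the modified image and the ground-truth metal mask. A zero-size
#' wire leaves the image unchanged and yields an empty mask.
#'
#' @param image an [image_slice()].
#' @param wire a [metal_wire_spec()]; its attenuation must exceed the
#'   image maximum and it must lie inside the field of view.
#' @return list with elements `image` (the embedded [image_slice()]) and
#'   `mask` (the exact `metal_mask`).
#' @export
embed_metal <- function(image, wire) {
  stopifnot(inherits(image, "image_slice"),
            inherits(wire, "metal_wire_spec"))
  g <- image$geometry
  fov_r <- g$image_size * g$pixel_size / 2
  extent <- wire$radius + wire$length / 2
  if (sqrt(sum(wire$center^2)) + extent > fov_r + 1e-9) {
    stop("wire extends outside the field of view", call. = FALSE)
  }
  if (wire$radius > 0 && wire$attenuation <= max(image$values)) {
    stop("wire attenuation (", wire$attenuation,
         ") must exceed the tissue maximum (", max(image$values), ")",
         call. = FALSE)
  }
  co <- grid_coords(g)
  dx <- outer(rep(1, g$image_size), co$x - wire$center[1])
  dy <- outer(co$y - wire$center[2], rep(1, g$image_size))
  if (wire$shape == "disk" || wire$length == 0) {
    inside <- (dx^2 + dy^2) < wire$radius^2
  } else {
    phi <- wire$angle_deg * pi / 180
    u <- dx * cos(phi) + dy * sin(phi)      # along the segment
    v <- -dx * sin(phi) + dy * cos(phi)     # across
    uc <- pmin(pmax(u, -wire$length / 2), wire$length / 2)
    inside <- ((u - uc)^2 + v^2) < wire$radius^2
  }
  vals <- image$values
  vals[inside] <- wire$attenuation
  mvals <- matrix(NA_real_, g$image_size, g$image_size)
  mvals[inside] <- wire$attenuation
  mask <- structure(list(support = inside, metal_values = mvals,
                         geometry = g),
                    class = "metal_mask")
  list(image = image_slice(vals, g), mask = mask)
}
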