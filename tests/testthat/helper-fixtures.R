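# Shared small fixtures. Everything is generated in code; sizes are kept
# small so the whole suite runs on one CPU in minutes.

# small geometry for fast reconstruction tests
small_geom <- function(n_views = 120, size = 64, n_bins = 96) {
  scan_geometry(n_views = n_views, angle_step_deg = 360 / n_views,
                n_bins = n_bins, image_size = size)
}

# uniform-disk image on a geometry's grid (area-antialiased)
disk_image <- function(geom, center = c(0, 0), radius = 20,
                       attenuation = 1) {
  generate_phantom(
    phantom_spec(list(center = center, axes = c(radius, radius),
                      value = attenuation),
                 noise_amplitude = 0),
    geom)
}

# deterministic two-class phantom
tissue_phantom <- function(geom, seed = 3) {
  generate_phantom(sample_phantom_spec(geom, seed = seed), geom)
}

# brute-force line integral of an image along the ray (s, theta),
# midpoint rule with bilinear interpolation; independent of the C++
# projector's traversal scheme
brute_force_ray <- function(img_vals, geom, s, theta, n_steps = 4000) {
  n <- geom$image_size
  px <- geom$pixel_size
  half_len <- n * px
  t <- seq(-half_len, half_len, length.out = n_steps)
  dt <- t[2] - t[1]
  x <- s * cos(theta) - t * sin(theta)
  y <- s * sin(theta) + t * cos(theta)
  i <- (n + 1) / 2 - y / px
  j <- x / px + (n + 1) / 2
  ok <- i >= 1 & i <= n & j >= 1 & j <= n
  if (!any(ok)) return(0)
  v <- sinomar:::cpp_bilinear_sample(img_vals, i[ok], j[ok])
  sum(v) * dt
}
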