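test_that("downsample_views keeps every factor-th view", {
  g <- scan_geometry()
  s <- sinogram(matrix(rep(1:360, each = 180), 180), g)
  d <- downsample_views(s, 4)
  expect_equal(d$geometry$n_views, 90)           # 360 -> 90
  expect_equal(d$geometry$angle_step_deg, 4)
  expect_equal(d$values[1, ], seq(1, 360, by = 4))
  expect_identical(downsample_views(s, 1), s)    # factor 1 is the identity
  expect_error(downsample_views(s, 7), "divisible")
  # 8 views, factor 2 retains original indices {1,3,5,7}
  g8 <- scan_geometry(n_views = 8, angle_step_deg = 45, n_bins = 96,
                      image_size = 64)
  s8 <- sinogram(matrix(rep(1:8, each = 96), 96), g8)
  expect_equal(downsample_views(s8, 2)$values[1, ], c(1, 3, 5, 7))
})

test_that("upsample_view_grid inserts invalid views at the right places", {
  g <- scan_geometry(n_views = 90, angle_step_deg = 4)
  s <- sinogram(matrix(runif(180 * 90), 180), g)
  u <- upsample_view_grid(s, 4)
  expect_equal(u$geometry$n_views, 360)          # 90 -> 360
  expect_equal(sum(!u$valid), 180 * 270)         # (factor-1)*n_views columns
  pos <- (seq_len(90) - 1) * 4 + 1
  expect_identical(u$values[, pos], s$values)
  expect_true(all(u$valid[, pos]))
  expect_identical(upsample_view_grid(s, 1), s)
})

test_that("downsample then upsample restores the retained views exactly", {
  g <- scan_geometry()
  set.seed(1)
  s <- forward_project(tissue_phantom(small_geom()))
  su <- upsample_view_grid(downsample_views(
    sinogram(matrix(runif(180 * 360), 180), g), 4), 4)
  orig <- sinogram(matrix(runif(180 * 360), 180), g)  # fresh random sinogram
  su2 <- upsample_view_grid(downsample_views(orig, 4), 4)
  keep <- seq(1, 360, by = 4)
  expect_identical(su2$values[, keep], orig$values[, keep])
})

test_that("linear interpolation recovers constant and affine sinograms", {
  g <- scan_geometry(n_views = 120, angle_step_deg = 3, n_bins = 96,
                     image_size = 64)
  # constant along views, every other view removed: exact recovery
  s <- sinogram(matrix(rep(sin(1:96), 120), 96), g)
  miss <- s
  miss$valid[, seq(2, 120, by = 2)] <- FALSE
  rec <- linear_interpolate(miss)
  expect_lt(max(abs(rec$values - s$values)), 1e-9)
  expect_true(all(rec$valid))
  # affine in the view index, x4 decimation: interior views are exact
  ramp <- sinogram(outer(rep(1, 96), seq(0, 11.9, by = 0.1)), g)
  m2 <- ramp
  m2$valid[, setdiff(1:120, seq(1, 120, by = 4))] <- FALSE
  r2 <- linear_interpolate(m2)
  interior <- 1:117   # beyond the last retained view the wrap kicks in
  expect_lt(max(abs(r2$values[, interior] - ramp$values[, interior])), 1e-9)
})

test_that("angular interpolation wraps across the 360-degree seam", {
  g <- scan_geometry(n_views = 8, angle_step_deg = 45, n_bins = 96,
                     image_size = 64)
  # a pure harmonic in the view angle is recovered well at the seam views
  th <- view_angles(g)
  s <- sinogram(outer(rep(1, 96), 5 + cos(th)), g)
  m <- s
  m$valid[, c(8)] <- FALSE    # last view missing: neighbours are 7 and 1
  r <- linear_interpolate(m)
  want <- (s$values[, 7] + s$values[, 1]) / 2
  expect_equal(r$values[, 8], want, tolerance = 1e-12)
})

test_that("metal-track gaps are bridged by two-point interpolation", {
  g <- small_geom()
  set.seed(4)
  s <- sinogram(matrix(runif(96 * 120, 1, 2), 96), g)
  m <- s
  gap <- 40:46
  m$valid[gap, 17] <- FALSE
  r <- linear_interpolate(m)
  # brute-force two-point oracle between the flanking bins 39 and 47
  lo <- s$values[39, 17]
  hi <- s$values[47, 17]
  for (k in seq_along(gap)) {
    want <- lo + (hi - lo) * k / 8
    expect_equal(r$values[gap[k], 17], want, tolerance = 1e-12)
  }
  # untouched entries are bit-identical
  expect_identical(r$values[-gap, 17], s$values[-gap, 17])
})

test_that("interpolation reports impossible completions", {
  g <- small_geom()
  s <- sinogram(matrix(1, 96, 120), g,
                matrix(FALSE, 96, 120))
  expect_error(linear_interpolate(s), "impossible")
})

test_that("unet_synthesize with an identity model returns its input and
           never touches measured bins", {
  g <- small_geom()
  net <- build_modified_unet(net_config("modified_unet", depth = 2,
                                        base_channels = 4), seed = 2)
  s <- forward_project(tissue_phantom(g))
  sp <- downsample_views(s, 4)
  up <- upsample_view_grid(sp, 4)
  init <- linear_interpolate(up)
  out <- unet_synthesize(init, net)
  # untrained network is the identity through its residual path
  expect_equal(out$values, init$values, tolerance = 1e-12)
  # measured bins restored verbatim even for a non-identity model
  net$params[[length(net$params) - 0]]$w[] <- 0  # keep final zero
  net$params[[1]]$w[] <- net$params[[1]]$w + 0.1
  out2 <- unet_synthesize(init, net)
  keep <- seq(1, 120, by = 4)
  expect_identical(out2$values[, keep], sp$values)
  # refuses un-initialized sinograms
  expect_error(unet_synthesize(up, net), "linear_interpolate")
})
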