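test_that("phantom rasterization matches analytic ellipse areas", {
  g <- scan_geometry()
  # zero-attenuation spec renders an all-zero image
  z <- generate_phantom(phantom_spec(list(center = c(0, 0), axes = c(10, 10),
                                          value = 0), noise_amplitude = 0), g)
  expect_true(all(z$values == 0))
  # one centered ellipse: rasterized area within 2% of pi*a*b
  a <- 40
  b <- 25
  ph <- generate_phantom(phantom_spec(list(center = c(0, 0), axes = c(a, b),
                                           angle_deg = 30, value = 1),
                                      noise_amplitude = 0), g)
  expect_lt(abs(sum(ph$values) - pi * a * b) / (pi * a * b), 0.02)
  expect_true(all(ph$values >= 0))
  expect_error(
    generate_phantom(phantom_spec(list(center = c(60, 0), axes = c(20, 5),
                                       value = 1)), g),
    "field of view")
})

test_that("phantom generation is deterministic under a fixed seed", {
  g <- small_geom()
  s1 <- sample_phantom_spec(g, seed = 12)
  s2 <- sample_phantom_spec(g, seed = 12)
  expect_identical(generate_phantom(s1, g)$values,
                   generate_phantom(s2, g)$values)
  s3 <- sample_phantom_spec(g, seed = 13)
  expect_false(identical(generate_phantom(s1, g)$values,
                         generate_phantom(s3, g)$values))
})

test_that("embed_metal rasterizes the wire and returns the exact mask", {
  g <- small_geom()
  ph <- tissue_phantom(g)
  # zero-size wire: image unchanged, empty mask
  z <- embed_metal(ph, metal_wire_spec(radius = 0))
  expect_identical(z$image$values, ph$values)
  expect_equal(sum(z$mask$support), 0)
  # disk wire: count equals the rasterized-disk pixel count, values set
  emb <- embed_metal(ph, metal_wire_spec(center = c(5.2, -3.7), radius = 3,
                                         attenuation = 50))
  co <- sinomar:::grid_coords(g)
  inside <- outer(co$y + 3.7, co$x - 5.2,
                  function(yy, xx) xx^2 + yy^2 < 9)
  expect_equal(sum(emb$mask$support), sum(inside))
  expect_true(all(emb$image$values[emb$mask$support] == 50))
  # cross-module: thresholding midway recovers exactly this mask
  seg <- segment_metal(emb$image, (max(ph$values) + 50) / 2)
  expect_identical(seg$support, emb$mask$support)
  # wire must dominate tissue and stay inside the grid
  expect_error(embed_metal(ph, metal_wire_spec(radius = 3,
                                               attenuation = 0.3)),
               "exceed")
  expect_error(embed_metal(ph, metal_wire_spec(center = c(40, 0),
                                               radius = 3)),
               "field of view")
  # capsule wires rasterize along their axis
  cap <- embed_metal(ph, metal_wire_spec("capsule", center = c(0, 0),
                                         radius = 1.5, length = 14,
                                         angle_deg = 45))
  expect_gt(sum(cap$mask$support), sum(emb$mask$support))
})

test_that("simulate_pair wires the simulation chain together", {
  g <- small_geom(n_views = 120)
  spec <- sample_phantom_spec(g, seed = 5)
  wire <- metal_wire_spec(center = c(6, 2), radius = 2.5)
  sp <- simulate_pair(spec, wire, g, decimation_factor = 4)
  expect_equal(sp$sparse_sino$geometry$n_views, 30)
  expect_equal(dim(sp$gt_sino$values), c(96, 120))
  expect_true(all(sp$metal_image$values[sp$metal_mask$support] == 50))
  # streaks: pixels above the tissue range outside the wire support
  tissue_max <- max(sp$gt_image$values)
  streaky <- sp$artifact_image$values > tissue_max & !sp$metal_mask$support
  expect_gt(sum(streaky), 0)
})

test_that("without a wire and without decimation the artifact image is
           plain FBP of the dense sinogram", {
  g <- small_geom(n_views = 120)
  spec <- sample_phantom_spec(g, seed = 6)
  sp <- simulate_pair(spec, NULL, g, decimation_factor = 1)
  expect_identical(sp$artifact_image$values,
                   fbp_reconstruct(sp$gt_sino)$values)
  expect_null(sp$metal_mask)
  # and the FBP agrees with the ground-truth phantom
  expect_lt(rmse(sp$artifact_image, sp$gt_image) /
              diff(range(sp$gt_image$values)), 0.05)
})

test_that("retained bins of the decimated-then-completed sinogram equal the
           dense sinogram away from the metal trace", {
  g <- small_geom(n_views = 120)
  sp <- simulate_pair(sample_phantom_spec(g, seed = 8),
                      metal_wire_spec(center = c(-4, 5), radius = 2), g, 4)
  up <- upsample_view_grid(sp$sparse_sino, 4)
  rm <- remove_metal(up, compute_metal_trace(sp$metal_mask, g))
  done <- linear_interpolate(rm)
  measured <- matrix(rep(seq_len(120), each = 96) %in% seq(1, 120, by = 4),
                     96, 120)
  keep <- rm$valid & measured
  expect_identical(done$values[keep], sp$dense_sino$values[keep])
})

test_that("larger wires leave larger metal traces", {
  g <- small_geom()
  ph <- tissue_phantom(g)
  areas <- vapply(c(1.5, 3, 5), function(r) {
    emb <- embed_metal(ph, metal_wire_spec(center = c(4, 4), radius = r))
    sum(compute_metal_trace(emb$mask, g)$support)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("generate_dataset is reproducible and mass-conserving", {
  g <- small_geom(n_views = 120)
  d1 <- generate_dataset(2, g, seed = 21,
                         wire = metal_wire_spec(radius = 2))
  d2 <- generate_dataset(2, g, seed = 21,
                         wire = metal_wire_spec(radius = 2))
  expect_identical(attr(d1, "manifest"), attr(d2, "manifest"))
  expect_identical(d1[[1]]$gt_image$values, d2[[1]]$gt_image$values)
  expect_identical(d1[[2]]$sparse_sino$values, d2[[2]]$sparse_sino$values)
  for (cs in d1) {
    mass <- colSums(cs$gt_sino$values) * g$bin_spacing
    expect_lt(diff(range(mass)) / mean(mass), 0.01)
  }
  # distinct cases get distinct phantoms
  expect_false(identical(d1[[1]]$gt_image$values, d1[[2]]$gt_image$values))
})
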