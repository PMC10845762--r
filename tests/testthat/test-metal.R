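# fixture: tissue phantom with an off-center metal disk
metal_case <- function(geom = small_geom(), r = 3, mu = 50,
                       center = c(8, -6)) {
  ph <- tissue_phantom(geom)
  emb <- embed_metal(ph, metal_wire_spec(center = center, radius = r,
                                         attenuation = mu))
  list(geom = geom, phantom = ph, image = emb$image, mask = emb$mask,
       center = center, r = r, mu = mu)
}

test_that("segment_metal thresholds with >= and handles empty masks", {
  g <- small_geom()
  img <- image_slice(matrix(1, 64, 64), g)
  expect_equal(sum(segment_metal(img, 5)$support), 0)
  # boundary pixel exactly at the threshold is included
  vals <- matrix(0, 64, 64)
  vals[10, 10] <- 5
  m <- segment_metal(image_slice(vals, g), 5)
  expect_true(m$support[10, 10])
  expect_equal(sum(m$support), 1)
  expect_equal(m$metal_values[10, 10], 5)
})

test_that("segmentation at the default-style threshold recovers the exact mask", {
  mc <- metal_case()
  thr <- (max(mc$phantom$values) + mc$mu) / 2
  m <- segment_metal(mc$image, thr)
  expect_identical(m$support, mc$mask$support)
  expect_equal(m$metal_values[m$support], mc$mask$metal_values[m$support])
})

test_that("segment_metal is idempotent on its own output", {
  mc <- metal_case()
  thr <- 25
  m1 <- segment_metal(mc$image, thr)
  as_img <- mc$image$values
  as_img[!m1$support] <- 0
  m2 <- segment_metal(image_slice(as_img, mc$geom), thr)
  expect_identical(m2$support, m1$support)
})

test_that("metal trace is empty iff the mask is empty, else spans all views", {
  g <- small_geom()
  empty <- segment_metal(image_slice(matrix(0, 64, 64), g), 1)
  tr <- compute_metal_trace(empty, g)
  expect_equal(sum(tr$support), 0)
  mc <- metal_case()
  tr2 <- compute_metal_trace(mc$mask, g)
  expect_true(all(colSums(tr2$support) > 0))
})

test_that("disk trace matches the analytic support within one bin per view", {
  mc <- metal_case()
  tr <- compute_metal_trace(mc$mask, mc$geom, dilate = 0)
  ana <- analytic_disk_trace(mc$center, mc$r, mc$geom)
  for (v in seq_len(mc$geom$n_views)) {
    got <- range(which(tr$support[, v]))
    want <- range(which(ana[, v]))
    expect_lte(abs(got[1] - want[1]), 1)
    expect_lte(abs(got[2] - want[2]), 1)
  }
})

test_that("trace support is monotone in the mask", {
  g <- small_geom()
  mc_small <- metal_case(g, r = 2)
  mc_large <- metal_case(g, r = 5)
  tr_s <- compute_metal_trace(mc_small$mask, g)
  tr_l <- compute_metal_trace(mc_large$mask, g)
  expect_true(all(tr_l$support[tr_s$support]))
  expect_gt(sum(tr_l$support), sum(tr_s$support))
})

test_that("remove_metal flags exactly the trace bins", {
  mc <- metal_case()
  s <- forward_project(mc$image)
  tr <- compute_metal_trace(mc$mask, mc$geom)
  out <- remove_metal(s, tr)
  expect_equal(sum(!out$valid), sum(tr$support))
  expect_identical(out$valid, !tr$support)
  expect_equal(out$values, s$values)   # values untouched, only flagged
  # empty trace leaves the sinogram unchanged
  g <- mc$geom
  empty_tr <- compute_metal_trace(
    segment_metal(image_slice(matrix(0, 64, 64), g), 1), g)
  out2 <- remove_metal(s, empty_tr)
  expect_true(all(out2$valid))
})

test_that("reinsert_metal is a pixelwise selector", {
  mc <- metal_case()
  den <- image_slice(matrix(0.1, 64, 64), mc$geom)
  out <- reinsert_metal(den, mc$mask)
  # brute-force elementwise oracle
  for (idx in sample(length(out$values), 200)) {
    want <- if (mc$mask$support[idx]) mc$mask$metal_values[idx] else 0.1
    expect_identical(out$values[idx], want)
  }
  # empty mask: identity
  empty <- segment_metal(image_slice(matrix(0, 64, 64), mc$geom), 1)
  expect_identical(reinsert_metal(den, empty)$values, den$values)
  # full-support mask: output equals the metal values
  full <- segment_metal(mc$image, min(mc$image$values))
  expect_identical(reinsert_metal(den, full)$values, mc$image$values)
})

test_that("reinsert after segment is the identity on the embedded image", {
  mc <- metal_case()
  m <- segment_metal(mc$image, 25)
  blurred <- image_slice(mc$image$values * 0.9, mc$geom)
  out <- reinsert_metal(blurred, m)
  expect_identical(out$values[m$support], mc$image$values[m$support])
  restored <- reinsert_metal(mc$image, m)
  expect_identical(restored$values, mc$image$values)
})
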