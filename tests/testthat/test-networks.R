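test_that("net_config validates patch size against depth", {
  cfg <- net_config("modified_unet")
  expect_equal(cfg$patch_size, 64L)   # sinogram network default
  cfg2 <- net_config("modified_resunet")
  expect_equal(cfg2$patch_size, 48L)  # image network default
  expect_error(net_config("modified_unet", depth = 3, patch_size = 36),
               "divisible")
  expect_error(build_modified_unet(net_config("modified_resunet")), "kind")
  expect_error(build_modified_resunet(net_config("modified_unet")), "kind")
})

test_that("one strided-convolution stage halves the spatial size", {
  set.seed(1)
  w <- array(rnorm(3 * 3 * 1 * 4, sd = 0.1), c(3, 3, 1, 4))
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  y <- sinomar:::cpp_conv_fwd(x, w, numeric(4), 2L, 1L)
  expect_equal(dim(y), c(32L, 32L, 4L, 1L))   # 64 -> 32
})

test_that("both architectures preserve input shape", {
  unet <- build_modified_unet(net_config("modified_unet", depth = 2,
                                         base_channels = 4), seed = 1)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  expect_equal(dim(nn_predict(unet, x)), dim(x))
  resu <- build_modified_resunet(net_config("modified_resunet", depth = 2,
                                            base_channels = 4), seed = 1)
  x48 <- array(runif(48 * 48 * 2), c(48, 48, 1, 2))
  expect_equal(dim(nn_predict(resu, x48)), dim(x48))   # 48x48 in, 48x48 out
  # any size divisible by 2^depth works, not just the patch default
  x32 <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_equal(dim(nn_predict(unet, x32)), dim(x32))
  expect_error(nn_predict(unet, array(0, c(30, 30, 1, 1))), "divisible")
})

test_that("zero-weight networks act as the identity via the residual path", {
  for (build in list(build_modified_unet, build_modified_resunet)) {
    kind <- if (identical(build, build_modified_unet)) "modified_unet"
            else "modified_resunet"
    p <- if (kind == "modified_unet") 64 else 48
    net <- build(net_config(kind, depth = 2, base_channels = 4), seed = 3)
    for (j in seq_along(net$params)) {
      net$params[[j]]$w[] <- 0
      net$params[[j]]$b[] <- 0
    }
    x <- array(runif(p * p), c(p, p, 1, 1))
    expect_identical(nn_predict(net, x), x)
  }
})

test_that("a freshly initialized network is the identity (zero final layer)", {
  net <- build_modified_unet(net_config("modified_unet", depth = 2,
                                        base_channels = 8), seed = 11)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  expect_identical(nn_predict(net, x), x)
})

test_that("the forward pass is deterministic for fixed weights", {
  net <- build_modified_resunet(net_config("modified_resunet", depth = 2,
                                           base_channels = 4), seed = 5)
  x <- array(runif(48 * 48), c(48, 48, 1, 1))
  expect_identical(nn_predict(net, x), nn_predict(net, x))
})

test_that("doubling base channels roughly quadruples stage conv parameters", {
  n1 <- count_params(build_modified_resunet(
    net_config("modified_resunet", depth = 2, base_channels = 8), seed = 1))
  n2 <- count_params(build_modified_resunet(
    net_config("modified_resunet", depth = 2, base_channels = 16), seed = 1))
  expect_gt(n2 / n1, 3.2)
  expect_lt(n2 / n1, 4.2)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- net_config("modified_unet", depth = 1, base_channels = 2,
                    patch_size = 8)
  net <- build_modified_unet(cfg, seed = 42)
  set.seed(1)
  for (j in seq_along(net$params)) {
    net$params[[j]]$w[] <- rnorm(length(net$params[[j]]$w), sd = 0.3)
    net$params[[j]]$b[] <- rnorm(length(net$params[[j]]$b), sd = 0.1)
  }
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  tgt <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  loss_of <- function(nn) {
    p <- sinomar:::nn_forward(nn, x)
    0.5 * sum((p - tgt)^2)
  }
  acts <- sinomar:::nn_forward(net, x, keep_acts = TRUE)
  grads <- sinomar:::nn_backward(net, acts, acts[[length(acts)]] - tgt)
  eps <- 1e-5
  set.seed(2)
  for (j in seq_along(net$params)) {
    for (fld in c("w", "b")) {
      arr <- net$params[[j]][[fld]]
      for (i in sample(length(arr), min(3, length(arr)))) {
        np <- net
        np$params[[j]][[fld]][i] <- arr[i] + eps
        f1 <- loss_of(np)
        np$params[[j]][[fld]][i] <- arr[i] - eps
        f0 <- loss_of(np)
        num <- (f1 - f0) / (2 * eps)
        expect_equal(grads[[j]][[fld]][i], num, tolerance = 1e-5)
      }
    }
  }
})
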