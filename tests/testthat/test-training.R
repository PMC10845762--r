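test_that("train_config presets mirror the published hyperparameters", {
  sino <- train_config("sino")
  expect_equal(sino$learning_rate, 0.00001)
  expect_equal(sino$epochs, 100L)
  expect_equal(sino$n_train_patches, 180000L)
  expect_equal(sino$n_val_patches, 18000L)
  img <- train_config("image")
  expect_equal(img$learning_rate, 0.001)
  expect_equal(img$epochs, 1300L)
  expect_equal(img$n_train_patches, 458640L)
  expect_equal(img$n_val_patches, 80000L)
  expect_equal(sino$optimizer, "adam")
  expect_equal(sino$loss, "rmse")
  expect_error(train_config("sino", n_train_patches = 10,
                            n_val_patches = 20))
})

test_that("extract_patches is reproducible and respects its weights", {
  set.seed(9)
  a <- matrix(runif(100 * 100), 100)
  b <- a + matrix(rnorm(100 * 100, sd = 0.1), 100)
  p1 <- extract_patches(a, b, 16, 20, "uniform", seed = 3)
  p2 <- extract_patches(a, b, 16, 20, "uniform", seed = 3)
  expect_identical(p1$input, p2$input)
  expect_identical(p1$positions, p2$positions)
  expect_equal(dim(p1$input), c(16, 16, 1, 20))
  # weights concentrated on one position: every patch lands there
  w <- matrix(0, 85, 85)
  w[40, 12] <- 1
  p3 <- extract_patches(a, b, 16, 10, list(w), seed = 1)
  expect_true(all(p3$positions$row == 40 & p3$positions$col == 12))
  expect_error(extract_patches(a, b, 16, 0), "positive")
  expect_error(extract_patches(a, b, 128, 5), "smaller")
})

test_that("artifact-energy sampling concentrates on high-error regions", {
  set.seed(10)
  a <- matrix(0, 120, 120)
  b <- a
  b[20:50, 60:100] <- 1          # the only input-target disagreement
  pa <- extract_patches(a, b, 16, 200, "artifact", seed = 2)
  pu <- extract_patches(a, b, 16, 200, "uniform", seed = 2)
  mad <- function(p) mean(abs(p$input - p$target))
  expect_gt(mad(pa), mad(pu))
})

test_that("training reduces the loss when the optimum is representable", {
  set.seed(21)
  imgs <- lapply(1:2, function(i) matrix(runif(80 * 80), 80))
  noisy <- lapply(imgs, function(m) m + matrix(rnorm(6400, sd = 0.1), 80))
  patches <- extract_patches(noisy, imgs, 16,  96, seed = 4)
  net <- build_modified_unet(net_config("modified_unet", depth = 1,
                                        base_channels = 4, patch_size = 16),
                             seed = 4)
  cfg <- desk_train_config("sino", n_train_patches = 80,
                           n_val_patches = 16, epochs = 6,
                           learning_rate = 3e-3, batch_size = 16, seed = 4)
  st <- train_model(net, patches, cfg)
  expect_length(st$train_loss, 6)
  expect_length(st$val_loss, 6)
  expect_lt(tail(st$train_loss, 1), st$train_loss[1] + 1e-12)
  # best validation never exceeds the identity initialization
  expect_lte(st$best_val, st$val_loss0)
  expect_true(st$model$trained)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(33)
  a <- matrix(runif(64 * 64), 64)
  b <- a * 0.9
  patches <- extract_patches(a, b, 8, 40, seed = 6)
  run <- function() {
    net <- build_modified_unet(net_config("modified_unet", depth = 1,
                                          base_channels = 2,
                                          patch_size = 8), seed = 7)
    train_model(net, patches,
                desk_train_config("sino", n_train_patches = 32,
                                  n_val_patches = 8, epochs = 3,
                                  batch_size = 8, seed = 7))
  }
  s1 <- run()
  s2 <- run()
  expect_identical(s1$model$params, s2$model$params)
  expect_identical(s1$val_loss, s2$val_loss)
})

test_that("training curves are written as epoch/train/val CSV", {
  set.seed(1)
  a <- matrix(runif(32 * 32), 32)
  patches <- extract_patches(a, a, 8, 24, seed = 1)
  net <- build_modified_unet(net_config("modified_unet", depth = 1,
                                        base_channels = 2, patch_size = 8),
                             seed = 1)
  st <- train_model(net, patches,
                    desk_train_config("sino", n_train_patches = 16,
                                      n_val_patches = 4, epochs = 2,
                                      batch_size = 8, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_curves(st, path)
  df <- read.csv(path)
  expect_equal(names(df), c("epoch", "train_loss", "val_loss"))
  expect_equal(nrow(df), 2)
})
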