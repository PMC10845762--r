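test_that("rmse matches a brute-force loop and its identities", {
  expect_equal(rmse(matrix(1, 4, 4), matrix(1, 4, 4)), 0)
  expect_equal(rmse(matrix(3, 5, 5), matrix(1, 5, 5)), 2)  # constant offset
  set.seed(5)
  a <- matrix(rnorm(25), 5)
  b <- matrix(rnorm(25), 5)
  brute <- 0
  for (i in 1:5) for (j in 1:5) brute <- brute + (a[i, j] - b[i, j])^2
  expect_equal(rmse(a, b), sqrt(brute / 25), tolerance = 1e-12)
  expect_equal(rmse(a, b), rmse(b, a))                     # symmetry
  roi <- roi_rect(a, 1:2, 1:3)
  expect_equal(rmse(a, b, roi), sqrt(mean((a[roi] - b[roi])^2)),
               tolerance = 1e-12)
  expect_error(rmse(a, matrix(0, 4, 4)), "differ")
})

test_that("psnr follows its definition and is scale invariant", {
  a <- matrix(0.5, 4, 4)
  expect_equal(psnr(a, a), Inf)
  # m_peak = 1, MSE = 0.01 -> 20 dB
  test <- matrix(c(1, rep(0, 99)), 10)
  ref <- test
  ref[2] <- 0.1 * sqrt(100 / 99) # tweak so MSE is exactly 0.01... no:
  # build it directly: difference of 0.1 everywhere gives MSE 0.01
  test <- matrix(0.9, 10, 10)
  test[1, 1] <- 1               # sets m_peak = 1
  ref <- test - 0.1
  ref[1, 1] <- 0.9              # keep difference 0.1 at every pixel
  expect_equal(psnr(test, ref), 20, tolerance = 1e-10)
  set.seed(2)
  x <- matrix(runif(64), 8)
  y <- matrix(runif(64), 8)
  expect_equal(psnr(3 * x, 3 * y), psnr(x, y), tolerance = 1e-10)
  # monotone: stronger independent noise lowers psnr
  set.seed(3)
  noise <- matrix(rnorm(64), 8)
  p <- vapply(c(0.01, 0.05, 0.2), function(s) psnr(x + s * noise, x),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("ssim matches a direct evaluation of its formula", {
  set.seed(8)
  a <- matrix(runif(64), 8)
  expect_equal(ssim(a, a), 1.0)
  b <- matrix(runif(64), 8)
  k1 <- 0.001
  k2 <- 0.03                      # the stated defaults
  m_e <- mean(a)
  m_r <- mean(b)
  v_e <- mean((a - m_e)^2)
  v_r <- mean((b - m_r)^2)
  cv <- mean((a - m_e) * (b - m_r))
  want <- ((2 * m_r * m_e + k1) * (2 * cv + k2)) /
    ((m_r^2 + m_e^2 + k1) * (v_r + v_e + k2))
  expect_equal(ssim(a, b), want, tolerance = 1e-12)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-14)  # symmetric
  expect_true(abs(ssim(a, b)) <= 1)
  # constant-zero pair: stabilizers prevent 0/0
  z <- matrix(0, 8, 8)
  expect_equal(ssim(z, z), 1.0)
  # scaled mode applies c = (k L)^2
  L <- diff(range(b))
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  want2 <- ((2 * m_r * m_e + c1) * (2 * cv + c2)) /
    ((m_r^2 + m_e^2 + c1) * (v_r + v_e + c2))
  expect_equal(ssim(a, b, mode = "scaled"), want2, tolerance = 1e-12)
})

test_that("cnr follows its definition, sign and guards", {
  img <- matrix(0, 10, 10)
  t_roi <- roi_rect(img, 1:5, 1:10)
  r_roi <- roi_rect(img, 6:10, 1:10)
  # means 2 vs 1, sds 0.5 each -> 1/sqrt(0.5)
  set.seed(1)
  mk <- function(m, s, n) {
    v <- rnorm(n)
    m + s * (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  img[t_roi] <- mk(2, 0.5, 50)
  img[r_roi] <- mk(1, 0.5, 50)
  expect_equal(cnr(img, t_roi, r_roi), 1 / sqrt(0.5), tolerance = 1e-10)
  expect_equal(cnr(img, r_roi, t_roi), -1 / sqrt(0.5), tolerance = 1e-10)
  # identical ROI statistics -> 0 (with 0/0 guard and warning)
  flat <- matrix(1, 10, 10)
  expect_warning(z <- cnr(flat, t_roi, r_roi), "0/0")
  expect_equal(z, 0)
  expect_error(cnr(img, t_roi, t_roi), "overlap")
  expect_error(cnr(img, matrix(FALSE, 10, 10), r_roi), "empty")
})

test_that("line_profile samples bilinearly between its endpoints", {
  img <- matrix(2.5, 20, 20)
  pr <- line_profile(img, c(3, 3), c(18, 11), 50)
  expect_equal(pr$value, rep(2.5, 50), tolerance = 1e-12)  # constant image
  expect_equal(nrow(pr), 50)
  # n_samples = 2 gives exactly the endpoint values
  img2 <- matrix(seq_len(400), 20)
  p2 <- line_profile(img2, c(4, 7), c(19, 2), 2)
  expect_equal(p2$value, c(img2[4, 7], img2[19, 2]))
  # across a vertical step edge the transition is monotone and bracketed
  step <- matrix(0, 20, 20)
  step[, 11:20] <- 1
  p3 <- line_profile(step, c(10, 5), c(10, 16), 40)
  expect_true(all(diff(p3$value) >= -1e-12))
  expect_true(all(p3$value >= 0 & p3$value <= 1))
  expect_error(line_profile(img, c(0, 5), c(10, 10)), "outside")
})

test_that("metric_report assembles one labelled row", {
  set.seed(2)
  a <- matrix(runif(64), 8)
  rep <- metric_report("fbp", a, a)
  expect_equal(rep$method, "fbp")
  expect_equal(rep$ssim, 1)
  expect_equal(rep$rmse, 0)
  expect_true(is.na(rep$cnr))
  expect_equal(names(rep), c("method", "ssim", "cnr", "psnr", "rmse"))
})
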