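test_that("U-Net maps a 2-channel volume to a 1-channel volume of equal shape", {
  m <- build_unet(unet_config(levels = 2, base_channels = 4), seed = 1)
  gd <- c(8L, 8L, 8L)
  y <- unet_predict(m, array(0.1, gd), array(-0.2, gd))
  expect_identical(dim(y), gd)
  expect_true(all(is.finite(y)))
})

test_that("forward pass rejects grids not divisible by 2^levels", {
  m <- build_unet(unet_config(levels = 2, base_channels = 4), seed = 1)
  expect_error(unet_forward(m, matrix(0, 9^3, 2), c(9, 9, 9)), "divisible")
})

test_that("parameter count grows with base channels and depth", {
  n1 <- n_parameters(build_unet(unet_config(2, 4), seed = 1))
  n2 <- n_parameters(build_unet(unet_config(2, 8), seed = 1))
  n3 <- n_parameters(build_unet(unet_config(3, 8), seed = 1))
  expect_lt(n1, n2)
  expect_lt(n2, n3)
})

test_that("inference is deterministic for fixed weights and input", {
  m <- build_unet(unet_config(2, 4), seed = 5)
  gd <- c(8, 8, 8)
  x1 <- array(stats::rnorm(prod(gd)), gd)
  x2 <- array(stats::rnorm(prod(gd)), gd)
  expect_identical(unet_predict(m, x1, x2), unet_predict(m, x1, x2))
  # same seed, same weights; different seed, different weights
  expect_identical(build_unet(unet_config(2, 4), seed = 5)$params, m$params)
  expect_false(identical(build_unet(unet_config(2, 4), seed = 6)$params,
                         m$params))
})

test_that("analytic gradients match finite differences through all layers", {
  set.seed(42)
  m <- build_unet(unet_config(levels = 2, base_channels = 4), seed = 3)
  gd <- c(8, 8, 8)
  V <- prod(gd)
  X <- matrix(stats::rnorm(V * 2), V, 2)
  truth <- stats::rnorm(V)
  msk <- as.numeric(stats::runif(V) > 0.3)
  Nm <- sum(msk)
  lossfn <- function(mm) {
    y <- unet_forward(mm, X, gd)$y
    sum(msk * (y - truth)^2) / Nm
  }
  fw <- unet_forward(m, X, gd, train = TRUE)
  gr <- unet_backward(m, fw$tape, matrix(2 * msk * (fw$y - truth) / Nm, ncol = 1))
  for (nm in c("enc1a_W", "enc2b_W", "up1_W", "dec1a_W", "dec1b_g", "out_W")) {
    p <- m$params[[nm]]
    i <- sample(length(p), 1)
    mp <- m; mp$params[[nm]][i] <- p[i] + 1e-5
    mm_ <- m; mm_$params[[nm]][i] <- p[i] - 1e-5
    num <- (lossfn(mp) - lossfn(mm_)) / 2e-5
    expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
  }
})

test_that("loss follows the truth/difference decomposition", {
  # masked 2-voxel toy: outputs (1,3) and (1,1) vs truth (1,1)
  # MSE1 = mean((0,2)^2) = 2, MSE2 = 0, diff = mean((0,2)^2) = 2
  # total = (2+0)/2 + 2 = 3
  gd <- c(8, 8, 8)
  mk <- array(0, gd); mk[1:2] <- 1
  o1 <- array(0, gd); o1[1:2] <- c(1, 3)
  o2 <- array(0, gd); o2[1:2] <- c(1, 1)
  tr <- array(0, gd); tr[1:2] <- c(1, 1)
  r <- compute_loss(list(o1, o2), tr, mk)
  expect_equal(r$truth_losses, c(2, 0))
  expect_equal(r$diff_loss, 2)
  expect_equal(r$total, 3)
  # single blip: total is the plain masked MSE
  r1 <- compute_loss(list(o1), tr, mk)
  expect_equal(r1$total, 2)
  expect_true(is.na(r1$diff_loss))
  # perfect prediction -> 0
  expect_equal(compute_loss(list(tr, tr), tr, mk)$total, 0)
  expect_error(compute_loss(list(o1), tr, array(0, gd)), "empty")
})

test_that("dual-blip loss equals the arithmetic identity on random tensors", {
  set.seed(11)
  for (rep in 1:25) {
    n <- 64
    mk <- stats::runif(n) > 0.4
    if (!any(mk)) mk[1] <- TRUE
    y1 <- stats::rnorm(n); y2 <- stats::rnorm(n); tr <- stats::rnorm(n)
    r <- compute_loss(list(y1, y2), tr, mk)
    mse1 <- mean((y1[mk] - tr[mk])^2)
    mse2 <- mean((y2[mk] - tr[mk])^2)
    msed <- mean((y1[mk] - y2[mk])^2)
    expect_equal(r$total, (mse1 + mse2) / 2 + msed, tolerance = 1e-12)
    expect_gte(r$total, mean(r$truth_losses))  # diff term is non-negative
  }
})

test_that("identical blips collapse the difference term", {
  set.seed(12)
  n <- 128
  y <- stats::rnorm(n); tr <- stats::rnorm(n)
  r <- compute_loss(list(y, y), tr, rep(TRUE, n))
  expect_equal(r$diff_loss, 0)
  expect_equal(r$total, mean(r$truth_losses))
})

test_that("ensemble mean equals the member mean and single member passthrough", {
  gd <- c(8, 8, 8)
  m1 <- build_unet(unet_config(2, 4), seed = 1)
  x1 <- array(stats::rnorm(prod(gd)), gd)
  x2 <- array(stats::rnorm(prod(gd)), gd)
  y1 <- unet_predict(m1, x1, x2)
  # k identical models = single model
  same <- synthesize_b0(list(m1, m1, m1), x1, x2,
                        geom = b0_volume(x1, c(1, 1, 1)))
  expect_equal(same$data, y1, tolerance = 1e-12)
  # members differing -> voxelwise mean
  m2 <- build_unet(unet_config(2, 4), seed = 2)
  y2 <- unet_predict(m2, x1, x2)
  avg <- synthesize_b0(list(m1, m2), x1, x2,
                       geom = b0_volume(x1, c(1, 1, 1)))
  expect_equal(avg$data, (y1 + y2) / 2, tolerance = 1e-12)
  expect_error(synthesize_b0(list(), x1, x2), "empty")
})
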