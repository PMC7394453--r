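test_that("gain matching equalizes masked medians", {
  s <- small_subject()
  mask <- s$mask
  # pure gain: u = 2*d must come back exactly to d
  d <- s$b0_u
  u <- b0_volume(2 * d$data, d$voxel_size, d$affine)
  out <- match_gain(u, d, mask)
  expect_equal(out$data, d$data, tolerance = 1e-12)
  # already matched -> identity
  out2 <- match_gain(d, d, mask)
  expect_equal(out2$data, d$data, tolerance = 1e-12)
  # known medians give the expected scale factor
  m <- mask$data > 0.5
  gd <- dim(d$data)
  u3 <- b0_volume(array(80, gd), d$voxel_size, d$affine)
  d3 <- b0_volume(array(100, gd), d$voxel_size, d$affine)
  expect_equal(match_gain(u3, d3, mask)$data[m][1], 80 * 1.25)
  z <- b0_volume(array(0, gd), d$voxel_size, d$affine)
  expect_error(match_gain(z, d3, mask), "degenerate")
})

test_that("T1 normalization maps 0/75/150 to -1/0/+1 and clips overflow", {
  gd <- c(8, 8, 8)
  vals <- array(0, gd)
  vals[1:4] <- c(0, 75, 150, 200)
  t1 <- b0_volume(vals, c(1, 1, 1))
  n <- normalize_t1(t1)
  expect_equal(n$data[1:3], c(-1, 0, 1))
  expect_equal(n$data[4], 1)  # clipped
  # round-trip exact for in-range values
  back <- denormalize_t1(n)
  expect_equal(back$data[1:3], c(0, 75, 150))
})

test_that("b0 normalization shares the distorted p99 and does not clip pileup", {
  gd <- c(8, 8, 8)
  set.seed(2)
  d <- b0_volume(array(stats::runif(prod(gd), 0, 100), gd), c(1, 1, 1))
  u <- b0_volume(d$data * 0.9, d$voxel_size, d$affine)
  nb <- normalize_b0_pair(d, others = list(truth = u))
  p99 <- nb$norm$p99
  expect_equal(p99, stats::quantile(d$data, 0.99, names = FALSE))
  # v = p99 -> +1, v = 0 -> -1, v = 1.5 p99 -> +2 (pileup stays unclipped)
  expect_equal(2 * c(p99, 0, 1.5 * p99) / p99 - 1, c(1, -1, 2))
  expect_gt(max(nb$b0_d$data), 1)  # the top percentile exceeds +1 unclipped
  # the paired volume uses the SAME p99 (intensity ratios preserved)
  expect_equal(nb$others$truth$data, 2 * u$data / p99 - 1, tolerance = 1e-12)
  # round-trip
  expect_equal(denormalize_b0(nb$b0_d, nb$norm)$data, d$data, tolerance = 1e-12)
  z <- b0_volume(array(0, gd), c(1, 1, 1))
  expect_error(normalize_b0_pair(z), "degenerate")
})

test_that("working-grid resampling is identity on identical grids", {
  s <- small_subject()
  tgt <- list(shape = dim(s$t1$data), voxel_size = s$t1$voxel_size,
              affine = s$t1$affine)
  r <- to_working_grid(s$t1, tgt)
  expect_equal(r$vol$data, s$t1$data, tolerance = 1e-10)
  expect_true(all(r$validity$data == 1))
})

test_that("round-trip resampling of a smooth volume stays within 2% of range", {
  # band-limited source on a fine subject grid (2 mm), feature scale 8 mm,
  # resampled to the 2.5 mm working grid and back over the same 80 mm FOV
  set.seed(6)
  src_gd <- c(40L, 40L, 40L)
  smooth <- b0_volume(gaussian_smooth_3d(array(rnorm(prod(src_gd)), src_gd), 4),
                      c(2, 2, 2))
  tgt <- working_grid(32, voxel_size_mm = 2.5)
  r <- to_working_grid(smooth, tgt)
  back <- from_working_grid(r$vol, r$transform)
  rng <- diff(range(smooth$data))
  # exclude the one-voxel rim where the inverse interpolation is one-sided
  core <- array(FALSE, src_gd)
  core[3:38, 3:38, 3:38] <- TRUE
  expect_lt(max(abs(back$data - smooth$data)[core]), 0.02 * rng)
})

test_that("validity masks flag out-of-field voxels and intersect correctly", {
  s <- small_subject()
  shifted <- s$t1
  shifted$affine[2, 4] <- shifted$affine[2, 4] + 16 * 2.5  # half-FOV shift
  tgt <- list(shape = dim(s$t1$data), voxel_size = s$t1$voxel_size,
              affine = s$t1$affine)
  r1 <- to_working_grid(s$t1, tgt)
  r2 <- to_working_grid(shifted, tgt)
  expect_lt(mean(r2$validity$data), 0.6)
  expect_gt(mean(r2$validity$data), 0.3)
  m <- make_sampling_mask(list(r1$validity, r2$validity))
  expect_equal(m$data, r1$validity$data * r2$validity$data)
  # idempotent under re-application
  expect_equal(make_sampling_mask(list(m, m))$data, m$data)
  zero <- b0_volume(array(0, dim(m$data)) + 1e-9, m$voxel_size, m$affine)
  expect_error(make_sampling_mask(list(m, zero)), "empty")
})

test_that("smoothness matching recovers the blurring kernel width", {
  s <- small_subject()
  ref_sigma <- 0.8
  ref <- b0_volume(gaussian_smooth_3d(s$b0_u$data, ref_sigma),
                   s$b0_u$voxel_size, s$b0_u$affine)
  out <- smooth_to_match(s$b0_u, ref)
  expect_lt(abs(out$sigma - ref_sigma), 0.15)
  stat_out <- smoothness_stat(out$vol$data)
  stat_ref <- smoothness_stat(ref$data)
  expect_lt(abs(stat_out - stat_ref) / stat_ref, 0.05)
  # already smoother than the reference -> identity
  idm <- smooth_to_match(ref, s$b0_u)
  expect_equal(idm$sigma, 0)
  expect_identical(idm$vol$data, ref$data)
  same <- smooth_to_match(s$b0_u, s$b0_u)
  expect_equal(same$sigma, 0)
})
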