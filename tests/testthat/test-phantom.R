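test_that("phantom generation is deterministic under its seed", {
  p <- phantom_params(shape = 24, seed = 42)
  a <- make_phantom(p)
  b <- make_phantom(p)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$b0_u$data, b$b0_u$data)
  p2 <- phantom_params(shape = 24, seed = 43)
  expect_false(identical(make_phantom(p2)$t1$data, a$t1$data))
})

test_that("noise-free phantom hits the configured tissue means exactly", {
  p <- phantom_params(shape = 24, seed = 5, noise_sd = 0)
  ph <- make_phantom(p)
  for (lab in 1:4) {
    sel <- ph$labels == lab
    expect_equal(mean(ph$t1$data[sel]), p$t1_means[lab], tolerance = 1e-12)
    expect_equal(mean(ph$b0_u$data[sel]), p$b0_means[lab], tolerance = 1e-12)
  }
  # contrast orderings: T1 white > gray > CSF; b0 CSF brightest
  expect_true(p$t1_means[3] > p$t1_means[2])
  expect_true(p$t1_means[2] > p$t1_means[1])
  expect_true(p$b0_means[1] > max(p$b0_means[2:4]))
})

test_that("b0 99th percentile captures CSF intensity", {
  p <- phantom_params(shape = 32, seed = 9)
  ph <- make_phantom(p)
  p99 <- stats::quantile(ph$b0_u$data, 0.99, names = FALSE)
  expect_lt(abs(p99 - p$b0_means[1]) / p$b0_means[1], 0.10)
})

test_that("grid below 16 voxels is rejected", {
  expect_error(phantom_params(shape = 12), "at least 16")
})

test_that("field respects amplitude, mask support and determinism", {
  p <- phantom_params(shape = 24, seed = 3)
  ph <- make_phantom(p)
  f1 <- make_field(p, ph$mask)
  f2 <- make_field(p, ph$mask)
  expect_identical(f1$field, f2$field)
  expect_lte(max(abs(f1$field)), p$field_amplitude_hz)
  expect_true(all(f1$field[ph$mask$data < 0.5] == 0))
  p0 <- phantom_params(shape = 24, seed = 3, field_amplitude_hz = 0)
  expect_true(all(make_field(p0, ph$mask)$field == 0))
})

test_that("displacement is polarity * field * readout in voxel units", {
  p <- phantom_params(shape = 24, seed = 3)
  ph <- make_phantom(p)
  fld <- make_field(p, ph$mask)
  fld$field[] <- 10  # 10 Hz everywhere
  d <- field_to_displacement(fld, pe_spec(2, 1, 0.05))
  expect_equal(unique(as.vector(d$shift)), 0.5)  # 10 Hz * 0.05 s
  d0 <- field_to_displacement(fld, pe_spec(2, 1, 0))
  expect_true(all(d0$shift == 0))
  dm <- field_to_displacement(fld, pe_spec(2, -1, 0.05))
  expect_equal(dm$shift, -d$shift)
})

test_that("pushforward is identity at zero shift and splats linearly", {
  s <- small_subject()
  d0 <- displacement_field(array(0, dim(s$b0_u$data)), pe_spec(2, 1, 0.05))
  expect_equal(apply_distortion(s$b0_u, d0)$data, s$b0_u$data)
  # single spike shifted +0.5 splits evenly between neighbours
  gd <- c(8, 8, 8)
  v <- array(0, gd); v[4, 3, 4] <- 10
  vol <- b0_volume(v, c(1, 1, 1))
  dc <- displacement_field(array(0.5, gd), pe_spec(2, 1, 0.05))
  out <- apply_distortion(vol, dc)$data
  expect_equal(out[4, 3, 4], 5)
  expect_equal(out[4, 4, 4], 5)
  expect_equal(sum(out), 10)
})

test_that("pushforward rejects shifts beyond the line extent", {
  gd <- c(8, 8, 8)
  vol <- b0_volume(array(1, gd), c(1, 1, 1))
  d <- displacement_field(array(9, gd), pe_spec(2, 1, 0.05))
  expect_error(apply_distortion(vol, d), "extent")
})

test_that("per-line mass is conserved through the distortion", {
  s <- small_subject2()
  for (b in s$blips) {
    sum_u <- apply(s$b0_u$data, c(1, 3), sum)
    sum_d <- apply(b$vol$data, c(1, 3), sum)
    expect_lt(max(abs(sum_d - sum_u)) / max(sum_u), 1e-4)
  }
})

test_that("opposite blips have exactly negated displacements and shared truth", {
  s <- small_subject2()
  expect_identical(s$truth_disp[[1]]$shift, -s$truth_disp[[2]]$shift)
  expect_equal(s$blips[[1]]$pe$polarity, -s$blips[[2]]$pe$polarity)
  expect_equal(s$blips[[1]]$pe$axis, s$blips[[2]]$pe$axis)
})

test_that("distortion vanishes in the zero-readout limit", {
  p <- phantom_params(shape = 24, seed = 13, n_hotspots = 0)
  s <- simulate_subject(p, pe_axis = 2, readout = 1e-4, n_blips = 1)
  # max displacement is amp * 1e-4 <= 5e-3 voxels; linear splat error is
  # bounded by shift * local intensity difference
  expect_lt(max(abs(s$blips[[1]]$vol$data - s$b0_u$data)),
            0.01 * max(s$b0_u$data))
})

test_that("cohorts are distinct per subject and reproducible per master seed", {
  p <- phantom_params(shape = 16, seed = 1)
  c1 <- simulate_cohort(4, p, seed = 10, blip_pattern = c(1L, 2L))
  c2 <- simulate_cohort(4, p, seed = 10, blip_pattern = c(1L, 2L))
  h <- function(s) digest_vol(s$b0_u$data)
  expect_identical(vapply(c1, h, character(1)), vapply(c2, h, character(1)))
  expect_equal(length(unique(vapply(c1, h, character(1)))), 4L)
  expect_equal(vapply(c1, function(s) length(s$blips), integer(1)),
               c(1L, 2L, 1L, 2L))
})
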