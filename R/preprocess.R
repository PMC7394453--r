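#' Gain-match an undistorted b0 to its distorted counterpart
#'
#' When the undistorted b0 comes from a separate acquisition its receiver
#' gain may differ from the distorted b0's.  The undistorted volume is
#' rescaled so its masked median equals the distorted volume's masked
#' median (the analogue of topup's `-scale` option).
#'
#' @param b0_u undistorted `b0_volume`.
#' @param b0_d distorted `b0_volume`.
#' @param mask binary `b0_volume`; medians are taken over mask voxels.
#' @return rescaled `b0_volume`.
#' @export
match_gain <- function(b0_u, b0_d, mask) {
  stopifnot_same_grid(b0_u, b0_d)
  m <- mask$data > 0.5
  if (!any(m)) stop("empty mask")
  med_u <- stats::median(b0_u$data[m])
  med_d <- stats::median(b0_d$data[m])
  if (med_u <= 0 || med_d <= 0)
    stop("degenerate image: masked median must be > 0 for gain matching")
  b0_volume(b0_u$data * (med_d / med_u), b0_u$voxel_size, b0_u$affine)
}

#' Normalize a T1 volume to the network's [-1, 1] input range
#'
#' Maps the fixed normalized-T1 intensity range 0-150 linearly onto
#' `[-1, 1]` (`v/75 - 1`) and clips overflow to +1.  Assumes the input is
#' already on the 0-150 convention (the phantom simulator emits this; real
#' data needs an external intensity normalization first).
#'
#' @param t1 `b0_volume`.
#' @return normalized `b0_volume`.
#' @export
normalize_t1 <- function(t1) {
  v <- pmin(pmax(t1$data / 75 - 1, -1), 1)
  b0_volume(v, t1$voxel_size, t1$affine)
}

#' Invert the T1 normalization for in-range values
#' @param t1n normalized `b0_volume`.
#' @return `b0_volume` on the 0-150 scale.
#' @export
denormalize_t1 <- function(t1n) {
  b0_volume((t1n$data + 1) * 75, t1n$voxel_size, t1n$affine)
}

#' Normalize a distorted b0 (and optionally paired volumes) by its 99th percentile
#'
#' The 99th percentile of the distorted b0 is computed (it lands in CSF, the
#' brightest diffusion-contrast tissue) and `0..p99` is mapped linearly onto
#' `[-1, 1]` via `v -> 2 v / p99 - 1`.  No upper clipping is applied: pileup
#' voxels may exceed +1, which is exactly why a min/max scaling would be
#' unstable.  The same p99 is applied to every paired volume so that the
#' distorted and undistorted intensities stay on a common scale.
#'
#' @param b0_d distorted `b0_volume` (p99 source).  May be a list of blip
#'   volumes, in which case p99 is computed over their pooled intensities.
#' @param others named list of `b0_volume`s to scale with the same p99
#'   (e.g. the undistorted truth), or `NULL`.
#' @return list(`b0_d` scaled volume or list, `others` scaled list,
#'   `norm` = list(p99)).
#' @export
normalize_b0_pair <- function(b0_d, others = NULL) {
  blips <- if (inherits(b0_d, "b0_volume")) list(b0_d) else b0_d
  pooled <- unlist(lapply(blips, function(v) as.vector(v$data)))
  p99 <- as.numeric(stats::quantile(pooled, 0.99, names = FALSE))
  if (!is.finite(p99) || p99 <= 0)
    stop("degenerate b0: 99th percentile must be > 0")
  scale1 <- function(v) b0_volume(2 * v$data / p99 - 1, v$voxel_size, v$affine)
  out_d <- lapply(blips, scale1)
  if (inherits(b0_d, "b0_volume")) out_d <- out_d[[1]]
  list(b0_d = out_d,
       others = if (is.null(others)) NULL else lapply(others, scale1),
       norm = list(p99 = p99))
}

#' Invert the b0 normalization
#' @param vn normalized `b0_volume`.
#' @param norm the `norm` element returned by [normalize_b0_pair()].
#' @return `b0_volume` in image units.
#' @export
denormalize_b0 <- function(vn, norm) {
  b0_volume((vn$data + 1) / 2 * norm$p99, vn$voxel_size, vn$affine)
}

#' Define a working-grid geometry
#'
#' @param shape grid dims.
#' @param voxel_size_mm isotropic voxel size (default 2.5 mm, the network's
#'   working resolution).
#' @return list(shape, voxel_size, affine) with an axis-aligned RAS affine
#'   centered at the world origin.
#' @export
working_grid <- function(shape, voxel_size_mm = 2.5) {
  shape <- as.integer(rep_len(shape, 3L))
  vox <- rep_len(voxel_size_mm, 3L)
  affine <- diag(c(vox, 1))
  affine[1:3, 4] <- -vox * (shape - 1) / 2
  list(shape = shape, voxel_size = vox, affine = affine)
}

# Trilinear interpolation of vol$data at (possibly fractional) 0-based
# voxel coordinates given as an N x 3 matrix.  Returns list(values, valid).
trilinear_sample <- function(data, ijk) {
  gd <- dim(data)
  i0 <- floor(ijk)
  f <- ijk - i0
  valid <- ijk[, 1] >= 0 & ijk[, 1] <= gd[1] - 1 &
    ijk[, 2] >= 0 & ijk[, 2] <= gd[2] - 1 &
    ijk[, 3] >= 0 & ijk[, 3] <= gd[3] - 1
  cl <- function(v, n) pmin(pmax(v, 0L), n - 1L)
  a0 <- cl(i0[, 1], gd[1]); a1 <- cl(i0[, 1] + 1, gd[1])
  b0 <- cl(i0[, 2], gd[2]); b1 <- cl(i0[, 2] + 1, gd[2])
  c0 <- cl(i0[, 3], gd[3]); c1 <- cl(i0[, 3] + 1, gd[3])
  lin <- function(a, b, c) 1 + a + b * gd[1] + c * gd[1] * gd[2]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  vals <-
    data[lin(a0, b0, c0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    data[lin(a1, b0, c0)] * fx * (1 - fy) * (1 - fz) +
    data[lin(a0, b1, c0)] * (1 - fx) * fy * (1 - fz) +
    data[lin(a1, b1, c0)] * fx * fy * (1 - fz) +
    data[lin(a0, b0, c1)] * (1 - fx) * (1 - fy) * fz +
    data[lin(a1, b0, c1)] * fx * (1 - fy) * fz +
    data[lin(a0, b1, c1)] * (1 - fx) * fy * fz +
    data[lin(a1, b1, c1)] * fx * fy * fz
  list(values = vals, valid = valid)
}

#' Resample a volume onto a working grid
#'
#' Trilinear resampling onto the target geometry through the two affines.
#' The forward/inverse transform pair is stored so results can be brought
#' back to subject space, and voxels whose source position falls outside
#' the input field of view are recorded in a validity mask.
#'
#' @param vol `b0_volume`.
#' @param target geometry from [working_grid()] (or another `b0_volume`,
#'   whose geometry is used).
#' @return list(`vol` resampled `b0_volume`, `transform` =
#'   list(forward, inverse, target), `validity` binary `b0_volume`).
#' @export
to_working_grid <- function(vol, target) {
  if (inherits(target, "b0_volume"))
    target <- list(shape = dim(target$data), voxel_size = target$voxel_size,
                   affine = target$affine)
  gd <- target$shape
  # map target voxel -> world -> source voxel
  fwd <- solve(vol$affine) %*% target$affine   # target grid -> source grid
  n <- prod(gd)
  ijk_t <- cbind(rep(seq_len(gd[1]) - 1, times = gd[2] * gd[3]),
                 rep(rep(seq_len(gd[2]) - 1, each = gd[1]), times = gd[3]),
                 rep(seq_len(gd[3]) - 1, each = gd[1] * gd[2]),
                 rep(1, n))
  ijk_s <- ijk_t %*% t(fwd)
  sm <- trilinear_sample(vol$data, ijk_s[, 1:3, drop = FALSE])
  if (!any(sm$valid)) stop("no overlap between source volume and target grid")
  out <- array(sm$values, gd)
  out[!array(sm$valid, gd)] <- 0
  list(vol = b0_volume(out, target$voxel_size, target$affine),
       transform = structure(list(forward = fwd, inverse = solve(fwd),
                                  source = list(shape = dim(vol$data),
                                                voxel_size = vol$voxel_size,
                                                affine = vol$affine),
                                  target = target),
                             class = "grid_transform"),
       validity = b0_volume(array(as.numeric(sm$valid), gd),
                            target$voxel_size, target$affine))
}

#' Resample a working-grid volume back to subject space
#'
#' Applies the inverse of a stored [to_working_grid()] transform.
#'
#' @param vol working-grid `b0_volume`.
#' @param transform a `grid_transform`.
#' @return `b0_volume` on the original subject grid.
#' @export
from_working_grid <- function(vol, transform) {
  src <- transform$source
  gd <- src$shape
  n <- prod(gd)
  ijk_s <- cbind(rep(seq_len(gd[1]) - 1, times = gd[2] * gd[3]),
                 rep(rep(seq_len(gd[2]) - 1, each = gd[1]), times = gd[3]),
                 rep(seq_len(gd[3]) - 1, each = gd[1] * gd[2]),
                 rep(1, n))
  ijk_t <- ijk_s %*% t(transform$inverse)
  sm <- trilinear_sample(vol$data, ijk_t[, 1:3, drop = FALSE])
  out <- array(sm$values, gd)
  out[!array(sm$valid, gd)] <- 0
  b0_volume(out, src$voxel_size, src$affine)
}

#' Intersect per-volume validity masks into the sampling mask
#'
#' The loss (and evaluation) mask is the voxelwise intersection of all
#' per-volume validity masks, so the network is never trained on regions
#' where resampling could not be done.
#'
#' @param masks list of binary `b0_volume`s on the working grid.
#' @return binary `b0_volume`.
#' @export
make_sampling_mask <- function(masks) {
  stopifnot(length(masks) >= 1)
  acc <- masks[[1]]$data > 0.5
  for (m in masks[-1]) {
    stopifnot_same_grid(masks[[1]], m, "masks")
    acc <- acc & (m$data > 0.5)
  }
  if (!any(acc)) stop("sampling mask is empty: no common valid region")
  b0_volume(array(as.numeric(acc), dim(acc)),
            masks[[1]]$voxel_size, masks[[1]]$affine)
}

#' Laplacian-energy smoothness statistic
#'
#' Mean squared 6-neighbour discrete Laplacian of a 3D array — the
#' criterion matched by [smooth_to_match()]: smoother images have lower
#' Laplacian energy.
#'
#' @param data 3D numeric array.
#' @return scalar statistic.
#' @export
smoothness_stat <- function(data) {
  lap <- array(0, dim(data))
  for (ax in 1:3)
    lap <- lap + axis_shift(data, 1L, ax) + axis_shift(data, -1L, ax) - 2 * data
  mean(lap^2)
}

#' Smooth a distorted b0 to match a reference's smoothness
#'
#' The synthesized b0 comes back from the working grid slightly smoothed by
#' interpolation; before field estimation the distorted b0 is smoothed to
#' match, so the estimator does not mistake a resolution difference for
#' displacement.  A 1D search over Gaussian sigma in [0, 1.5] voxels
#' minimizes the absolute difference of the Laplacian-energy smoothness
#' statistic between output and reference.  If the input is already
#' smoother than the reference, sigma 0 (identity) is returned.
#'
#' @param b0_d `b0_volume` to smooth.
#' @param reference `b0_volume` whose smoothness is the target.
#' @return list(`vol` smoothed `b0_volume`, `sigma`).
#' @export
smooth_to_match <- function(b0_d, reference) {
  stopifnot_same_grid(b0_d, reference)
  target <- smoothness_stat(reference$data)
  if (smoothness_stat(b0_d$data) <= target)
    return(list(vol = b0_d, sigma = 0))
  obj <- function(s) abs(smoothness_stat(gaussian_smooth_3d(b0_d$data, s)) - target)
  opt <- stats::optimize(obj, c(0, 1.5))
  sigma <- opt$minimum
  list(vol = b0_volume(gaussian_smooth_3d(b0_d$data, sigma),
                       b0_d$voxel_size, b0_d$affine),
       sigma = sigma)
}
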