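# Internal numerical helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Shift a 3D array by `o` voxels along `axis`, replicating edge values.
axis_shift <- function(arr, o, axis) {
  if (o == 0) return(arr)
  n <- dim(arr)[axis]
  idx <- pmin(pmax(seq_len(n) + o, 1L), n)
  sel <- list(TRUE, TRUE, TRUE)
  sel[[axis]] <- idx
  do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Convolves along each axis with a normalized, truncated (3 sigma)
#' Gaussian kernel; sigma is in voxels, scalar or per-axis.  Edges
#' replicate, so constants are preserved exactly.
#'
#' @param arr 3D numeric array.
#' @param sigma kernel sigma in voxels (scalar or length 3); 0 skips an axis.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  out <- arr
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gaussian_kernel_1d(sigma[ax])
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim(arr))
    for (t in seq_along(k))
      acc <- acc + k[t] * axis_shift(out, t - r - 1L, ax)
    out <- acc
  }
  out
}

# Voxel-center coordinate arrays normalized to [-1, 1] per axis.
unit_coords <- function(gd) {
  cc <- lapply(1:3, function(a) {
    n <- gd[a]
    if (n == 1) 0 else (seq_len(n) - 1) / (n - 1) * 2 - 1
  })
  list(
    x = array(rep(cc[[1]], times = gd[2] * gd[3]), gd),
    y = array(rep(rep(cc[[2]], each = gd[1]), times = gd[3]), gd),
    z = array(rep(cc[[3]], each = gd[1] * gd[2]), gd)
  )
}

# Forward difference along an axis (last slice gets 0).
forward_diff <- function(arr, axis) {
  axis_shift_zero <- axis_shift(arr, 1L, axis)
  d <- axis_shift_zero - arr
  n <- dim(arr)[axis]
  sel <- list(TRUE, TRUE, TRUE)
  sel[[axis]] <- n
  d <- do.call(`[<-`, c(list(d), sel, list(value = 0)))
  d
}

# Central difference along an axis (one-sided at the ends).
central_diff <- function(arr, axis) {
  n <- dim(arr)[axis]
  fwd <- axis_shift(arr, 1L, axis)
  bwd <- axis_shift(arr, -1L, axis)
  d <- (fwd - bwd) / 2
  sel1 <- list(TRUE, TRUE, TRUE); sel1[[axis]] <- 1L
  seln <- list(TRUE, TRUE, TRUE); seln[[axis]] <- n
  # one-sided at boundaries (replicated shift already gives half-difference)
  d <- do.call(`[<-`, c(list(d), sel1, list(value = do.call(`[`, c(list(fwd - arr), sel1, list(drop = FALSE))))))
  d <- do.call(`[<-`, c(list(d), seln, list(value = do.call(`[`, c(list(arr - bwd), seln, list(drop = FALSE))))))
  d
}
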