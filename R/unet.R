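#' 3D U-Net configuration
#'
#' The synthesizer is an encoder-decoder with skip connections: two input
#' channels (normalized T1, normalized distorted b0) and one output channel
#' (synthesized undistorted b0).  Every 3x3x3 convolution is followed by
#' per-instance feature normalization and leaky rectification; instance norm
#' (rather than batch norm) because batches are small, leaky ReLU (rather
#' than ReLU) for gradient flow through the mostly-negative background.
#'
#' @param levels encoder depth (>= 2); each level halves the grid.
#' @param base_channels channels at the finest level (>= 4), doubled per level.
#' @param leaky_slope negative-part slope of the leaky ReLU.
#' @return object of class `unet_config`.
#' @export
unet_config <- function(levels = 3L, base_channels = 16L, leaky_slope = 0.01) {
  levels <- as.integer(levels)
  base_channels <- as.integer(base_channels)
  if (levels < 2L) stop("levels must be >= 2")
  if (base_channels < 4L) stop("base_channels must be >= 4")
  structure(list(in_channels = 2L, out_channels = 1L, levels = levels,
                 base_channels = base_channels, leaky_slope = leaky_slope),
            class = "unet_config")
}

unet_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$levels) - 1L)

init_conv <- function(params, name, cin, cout, with_norm = TRUE) {
  fan_in <- 27L * cin
  params[[paste0(name, "_W")]] <-
    matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  params[[paste0(name, "_b")]] <- numeric(cout)
  if (with_norm) {
    params[[paste0(name, "_g")]] <- rep(1, cout)
    params[[paste0(name, "_be")]] <- numeric(cout)
  }
  params
}

#' Build a 3D U-Net with freshly initialized weights
#'
#' He-style initialization, fully determined by `seed`.
#'
#' @param cfg a [unet_config].
#' @param seed integer seed for the weight draw.
#' @return object of class `unet_model`: list(`cfg`, `params`).
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- unet_channels(cfg)
  L <- cfg$levels
  with_seed(seed, {
    params <- list()
    cin <- cfg$in_channels
    for (l in seq_len(L)) {
      params <- init_conv(params, paste0("enc", l, "a"), cin, ch[l])
      params <- init_conv(params, paste0("enc", l, "b"), ch[l], ch[l])
      cin <- ch[l]
    }
    for (l in rev(seq_len(L - 1))) {
      params <- init_conv(params, paste0("up", l), ch[l + 1], ch[l], with_norm = FALSE)
      params <- init_conv(params, paste0("dec", l, "a"), 2L * ch[l], ch[l])
      params <- init_conv(params, paste0("dec", l, "b"), ch[l], ch[l])
    }
    params$out_W <- matrix(stats::rnorm(ch[1], sd = sqrt(1 / ch[1])), ch[1], 1)
    params$out_b <- 0
    structure(list(cfg = cfg, params = params), class = "unet_model")
  })
}

#' Number of trainable parameters of a U-Net
#' @param model `unet_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

check_unet_grid <- function(cfg, gd) {
  if (any(gd %% (2L^cfg$levels) != 0L))
    stop("grid dims (", paste(gd, collapse = "x"),
         ") must be divisible by 2^levels = ", 2L^cfg$levels)
}

conv_block_forward <- function(x, params, name, gi, slope, train) {
  cv <- conv3_forward(x, params[[paste0(name, "_W")]],
                      params[[paste0(name, "_b")]], gi)
  ino <- inorm_forward(cv$Y, params[[paste0(name, "_g")]],
                       params[[paste0(name, "_be")]])
  lr <- lrelu_forward(ino$Y, slope)
  cache <- if (train)
    list(COLS = cv$COLS, Xhat = ino$Xhat, istd = ino$istd, pos = lr$pos,
         Cin = ncol(x))
  list(y = lr$Y, cache = cache)
}

conv_block_backward <- function(dY, params, name, cache, gi, slope, grads) {
  dY <- lrelu_backward(dY, cache$pos, slope)
  ino <- inorm_backward(dY, cache$Xhat, cache$istd, params[[paste0(name, "_g")]])
  grads[[paste0(name, "_g")]] <- ino$dgamma
  grads[[paste0(name, "_be")]] <- ino$dbeta
  cv <- conv3_backward(ino$dX, cache$COLS, params[[paste0(name, "_W")]],
                       cache$Cin, gi)
  grads[[paste0(name, "_W")]] <- cv$dW
  grads[[paste0(name, "_b")]] <- cv$db
  list(dX = cv$dX, grads = grads)
}

# Forward pass.  X: V x 2 feature matrix on grid gd.  Returns list(y, tape);
# the tape holds everything backward needs (NULL caches when train = FALSE).
unet_forward <- function(model, X, gd, train = FALSE) {
  cfg <- model$cfg
  check_unet_grid(cfg, gd)
  params <- model$params
  L <- cfg$levels
  slope <- cfg$leaky_slope
  gis <- vector("list", L)
  g <- gd
  for (l in seq_len(L)) {
    gis[[l]] <- grid_indices(g)
    g <- g %/% 2L
  }
  tape <- list(gis = gis, blocks = list())
  enc <- vector("list", L)
  x <- X
  for (l in seq_len(L)) {
    if (l > 1L) x <- pool_forward(x, gis[[l - 1]]$CHILD)
    for (blk in c("a", "b")) {
      nm <- paste0("enc", l, blk)
      r <- conv_block_forward(x, params, nm, gis[[l]], slope, train)
      tape$blocks[[nm]] <- r$cache
      x <- r$y
    }
    enc[[l]] <- x
  }
  for (l in rev(seq_len(L - 1))) {
    xu <- upsample_forward(x, gis[[l]]$PARENT)
    nmu <- paste0("up", l)
    cv <- conv3_forward(xu, params[[paste0(nmu, "_W")]],
                        params[[paste0(nmu, "_b")]], gis[[l]])
    if (train)
      tape$blocks[[nmu]] <- list(COLS = cv$COLS, Cin = ncol(xu))
    x <- cbind(enc[[l]], cv$Y)
    for (blk in c("a", "b")) {
      nm <- paste0("dec", l, blk)
      r <- conv_block_forward(x, params, nm, gis[[l]], slope, train)
      tape$blocks[[nm]] <- r$cache
      x <- r$y
    }
  }
  y <- x %*% params$out_W + params$out_b
  if (train) tape$last_hidden <- x
  list(y = y, tape = tape)
}

# Backward pass for a scalar loss with gradient dY (V x 1) at the output.
# Returns the named gradient list matching model$params.
unet_backward <- function(model, tape, dY) {
  cfg <- model$cfg
  params <- model$params
  L <- cfg$levels
  slope <- cfg$leaky_slope
  ch <- unet_channels(cfg)
  gis <- tape$gis
  grads <- list()
  grads$out_W <- crossprod(tape$last_hidden, dY)
  grads$out_b <- sum(dY)
  dx <- dY %*% t(params$out_W)
  enc_grad <- vector("list", L)
  for (l in seq_len(L - 1)) {
    for (blk in c("b", "a")) {
      nm <- paste0("dec", l, blk)
      r <- conv_block_backward(dx, params, nm, tape$blocks[[nm]], gis[[l]],
                               slope, grads)
      grads <- r$grads
      dx <- r$dX
    }
    # split concat: first ch[l] columns feed the skip, the rest the up path
    dskip <- dx[, seq_len(ch[l]), drop = FALSE]
    enc_grad[[l]] <- if (is.null(enc_grad[[l]])) dskip else enc_grad[[l]] + dskip
    dup <- dx[, ch[l] + seq_len(ch[l]), drop = FALSE]
    nmu <- paste0("up", l)
    cv <- conv3_backward(dup, tape$blocks[[nmu]]$COLS,
                         params[[paste0(nmu, "_W")]],
                         tape$blocks[[nmu]]$Cin, gis[[l]])
    grads[[paste0(nmu, "_W")]] <- cv$dW
    grads[[paste0(nmu, "_b")]] <- cv$db
    dx <- upsample_backward(cv$dX, gis[[l]]$PARENT)
  }
  enc_grad[[L]] <- dx
  for (l in rev(seq_len(L))) {
    dx <- enc_grad[[l]]
    for (blk in c("b", "a")) {
      nm <- paste0("enc", l, blk)
      r <- conv_block_backward(dx, params, nm, tape$blocks[[nm]], gis[[l]],
                               slope, grads)
      grads <- r$grads
      dx <- r$dX
    }
    if (l > 1L) {
      dpool <- pool_backward(dx, gis[[l - 1]]$CHILD, gis[[l - 1]]$V)
      enc_grad[[l - 1]] <- enc_grad[[l - 1]] + dpool
    }
  }
  grads
}

#' Run a U-Net on normalized input volumes
#'
#' Convenience wrapper stacking the two input channels and reshaping the
#' output back to a 3D array.  Inference only (no gradient tape).
#'
#' @param model `unet_model`.
#' @param t1_norm,b0_d_norm normalized `b0_volume`s (or 3D arrays).
#' @return 3D array, the synthesized (still normalized) b0.
#' @export
unet_predict <- function(model, t1_norm, b0_d_norm) {
  a1 <- if (inherits(t1_norm, "b0_volume")) t1_norm$data else t1_norm
  a2 <- if (inherits(b0_d_norm, "b0_volume")) b0_d_norm$data else b0_d_norm
  stopifnot(identical(dim(a1), dim(a2)))
  gd <- dim(a1)
  X <- cbind(as.vector(a1), as.vector(a2))
  out <- unet_forward(model, X, gd, train = FALSE)
  array(out$y, gd)
}
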