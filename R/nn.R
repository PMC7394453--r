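# Minimal 3D convolutional network engine.
#
# Volumes are handled as V x C feature matrices (V voxels in column-major
# grid order, C channels).  3x3x3 convolutions are evaluated as an im2col
# gather through precomputed index tables followed by one BLAS matrix
# product; the backward input gradient reuses the same tables with the
# offsets flipped (a gather, never a scatter), so the whole engine is
# exact, deterministic and fast enough for desk-scale training on one CPU.
# Index tables are memoized per grid shape and channel count.

.nn_cache <- new.env(parent = emptyenv())

grid_indices <- function(gd) {
  key <- paste(gd, collapse = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  n1 <- gd[1]; n2 <- gd[2]; n3 <- gd[3]
  V <- prod(gd)
  i1 <- rep_len(seq_len(n1), V)
  i2 <- rep(rep(seq_len(n2), each = n1), times = n3)
  i3 <- rep(seq_len(n3), each = n1 * n2)
  offs <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  NBR <- matrix(0L, V, 27L)
  BAD <- vector("list", 27L)  # out-of-grid rows per tap (zero padding)
  for (k in 1:27) {
    j1 <- i1 + offs[k, 1]; j2 <- i2 + offs[k, 2]; j3 <- i3 + offs[k, 3]
    ok <- j1 >= 1 & j1 <= n1 & j2 >= 1 & j2 <= n2 & j3 >= 1 & j3 <= n3
    lin <- j1 + (j2 - 1) * n1 + (j3 - 1) * n1 * n2
    lin[!ok] <- 1  # clamped; BAD rows are zeroed after the gather
    NBR[, k] <- as.integer(lin)
    BAD[[k]] <- which(!ok)
  }
  res <- list(gd = gd, V = V, NBR = NBR, BAD = BAD)
  if (all(gd %% 2L == 0L)) {
    gdc <- gd %/% 2L
    Vc <- prod(gdc)
    p1 <- rep_len(seq_len(gdc[1]), Vc)
    p2 <- rep(rep(seq_len(gdc[2]), each = gdc[1]), times = gdc[3])
    p3 <- rep(seq_len(gdc[3]), each = gdc[1] * gdc[2])
    CHILD <- matrix(0L, Vc, 8L)
    k <- 1L
    for (c3 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
      f1 <- 2L * p1 - 1L + c1; f2 <- 2L * p2 - 1L + c2; f3 <- 2L * p3 - 1L + c3
      CHILD[, k] <- as.integer(f1 + (f2 - 1L) * n1 + (f3 - 1L) * n1 * n2)
      k <- k + 1L
    }
    q1 <- (i1 + 1L) %/% 2L; q2 <- (i2 + 1L) %/% 2L; q3 <- (i3 + 1L) %/% 2L
    PARENT <- as.integer(q1 + (q2 - 1L) * gdc[1] + (q3 - 1L) * gdc[1] * gdc[2])
    res$CHILD <- CHILD
    res$PARENT <- PARENT
    res$gdc <- gdc
  }
  .nn_cache[[key]] <- res
  res
}

conv3_forward <- function(X, W, b, gi) {
  V <- nrow(X); C <- ncol(X)
  COLS <- matrix(0, V, 27L * C)
  for (k in 1:27) {
    blk <- X[gi$NBR[, k], , drop = FALSE]
    if (length(gi$BAD[[k]])) blk[gi$BAD[[k]], ] <- 0
    COLS[, ((k - 1L) * C + 1L):(k * C)] <- blk
  }
  Y <- COLS %*% W
  Y <- Y + rep(b, each = V)
  list(Y = Y, COLS = COLS)
}

# Rearrange a conv weight (27 Cin) x Cout into the kernel of the adjoint
# convolution (27 Cout) x Cin: taps spatially flipped, channels transposed.
flip_kernel <- function(W, Cin, Cout) {
  Wf <- matrix(0, 27L * Cout, Cin)
  for (k in 1:27) {
    blk <- W[((27L - k) * Cin + 1L):((28L - k) * Cin), , drop = FALSE]
    Wf[((k - 1L) * Cout + 1L):(k * Cout), ] <- t(blk)
  }
  Wf
}

conv3_backward <- function(dY, COLS, W, Cin, gi) {
  dW <- crossprod(COLS, dY)
  db <- colSums(dY)
  # the input gradient is the convolution of dY with the flipped kernel,
  # so the forward gather + one GEMM computes it exactly
  Wf <- flip_kernel(W, Cin, ncol(dY))
  dX <- conv3_forward(dY, Wf, numeric(Cin), gi)$Y
  list(dX = dX, dW = dW, db = db)
}

inorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  V <- nrow(X)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = V)
  v <- colMeans(Xc * Xc)
  istd <- 1 / sqrt(v + eps)
  Xhat <- Xc * rep(istd, each = V)
  Y <- Xhat * rep(gamma, each = V) + rep(beta, each = V)
  list(Y = Y, Xhat = Xhat, istd = istd)
}

inorm_backward <- function(dY, Xhat, istd, gamma) {
  V <- nrow(dY)
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- dY * rep(gamma, each = V)
  m1 <- colMeans(dXhat)
  m2 <- colMeans(dXhat * Xhat)
  dX <- (dXhat - rep(m1, each = V) - Xhat * rep(m2, each = V)) *
    rep(istd, each = V)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

lrelu_forward <- function(X, slope) {
  pos <- X > 0
  list(Y = X * (slope + (1 - slope) * pos), pos = pos)
}

lrelu_backward <- function(dY, pos, slope) {
  dY * (slope + (1 - slope) * pos)
}

pool_forward <- function(X, CHILD) {
  Y <- X[CHILD[, 1], , drop = FALSE]
  for (k in 2:8) Y <- Y + X[CHILD[, k], , drop = FALSE]
  Y / 8
}

pool_backward <- function(dY, CHILD, Vfine) {
  dX <- matrix(0, Vfine, ncol(dY))
  g <- dY / 8
  for (k in 1:8) dX[CHILD[, k], ] <- g
  dX
}

upsample_forward <- function(X, PARENT) X[PARENT, , drop = FALSE]

upsample_backward <- function(dY, PARENT) {
  # PARENT covers 1..Vc, each 8 times; rowsum orders by sorted group = 1..Vc
  rowsum(dY, PARENT)
}
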