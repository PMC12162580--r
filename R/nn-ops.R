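# Minimal CNN engine.
#
# Feature maps are 4-D arrays dim (H, W, N, C).  Convolutions are stride-1
# with zero same-padding, lowered to one BLAS gemm through the compiled
# im2col/col2im kernels.  Every forward returns (out, cache); the matching
# backward consumes (dout, cache) and returns input/parameter gradients.
# Correctness of the hand-derived backwards is pinned by finite-difference
# gradient checks in the test suite.

.convFwd <- function(x, W, b, key = NULL) {
  d <- dim(x)
  k <- dim(W)[1]
  Cout <- dim(W)[4]
  if (k == 1L) {
    cols <- x                     # 1x1 conv: the patch matrix is a reshape
    dim(cols) <- c(d[1] * d[2] * d[3], d[4])
  } else {
    cols <- .im2colBuf(key, x, k)
  }
  out <- cols %*% matrix(W, ncol = Cout)
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(d[1], d[2], d[3], Cout)
  list(out = out, cols = cols, xdim = d, k = k)
}

.convBwd <- function(dout, cache, W) {
  k <- dim(W)[1]
  Cin <- dim(W)[3]
  Cout <- dim(W)[4]
  dm <- matrix(dout, ncol = Cout)
  dW <- crossprod(cache$cols, dm)
  dim(dW) <- dim(W)
  db <- colSums(dm)
  dcols <- dm %*% t(matrix(W, ncol = Cout))
  d <- cache$xdim
  if (k == 1L) {
    dx <- dcols
    dim(dx) <- d
  } else {
    dx <- .col2im_nn(dcols, d[1], d[2], d[3], Cin, k)
  }
  list(dx = dx, dW = dW, db = db)
}

.reluFwd <- function(x) list(out = pmax(x, 0), pos = x > 0)
.reluBwd <- function(dout, cache) dout * cache$pos

.poolFwd <- function(x) {
  r <- .maxpool2_nn(x)
  list(out = r$out, idx = r$idx, xdim = dim(x))
}
.poolBwd <- function(dout, cache) .maxpool2_bwd_nn(dout, cache$idx, cache$xdim)

# 2x2 transposed convolution, stride 2: each input pixel populates a 2x2
# output block; weights dim (2, 2, Cin, Cout), bias added once.
.upconvFwd <- function(x, W, b) {
  d <- dim(x)
  Cin <- d[4]; Cout <- dim(W)[4]
  H2 <- 2L * d[1]; W2 <- 2L * d[2]
  xm <- matrix(x, ncol = Cin)
  out <- array(0, c(H2, W2, d[3], Cout))
  for (i in 1:2) for (j in 1:2) {
    y <- xm %*% matrix(W[i, j, , ], Cin, Cout)
    dim(y) <- c(d[1], d[2], d[3], Cout)
    out[seq(i, H2, 2), seq(j, W2, 2), , ] <- y
  }
  out <- out + rep(b, each = H2 * W2 * d[3])
  list(out = out, xm = xm, xdim = d)
}

.upconvBwd <- function(dout, cache, W) {
  d <- cache$xdim
  Cin <- d[4]; Cout <- dim(W)[4]
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  dW <- array(0, dim(W))
  dxm <- matrix(0, nrow(cache$xm), Cin)
  for (i in 1:2) for (j in 1:2) {
    dy <- matrix(dout[seq(i, H2, 2), seq(j, W2, 2), , ], ncol = Cout)
    dW[i, j, , ] <- crossprod(cache$xm, dy)
    dxm <- dxm + dy %*% t(matrix(W[i, j, , ], Cin, Cout))
  }
  db <- colSums(matrix(dout, ncol = Cout))
  dx <- dxm
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# channel concatenation (skip first, then decoder path): C is the last dim
.concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(c(a, b), c(da[1], da[2], da[3], da[4] + db[4]))
  out
}

.splitC <- function(d, c1) {
  list(a = d[, , , seq_len(c1), drop = FALSE],
       b = d[, , , -seq_len(c1), drop = FALSE])
}

# global average pool over (H, W): (H,W,N,C) -> (N, C)
.gapFwd <- function(x) {
  d <- dim(x)
  s <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  list(out = matrix(s, d[3], d[4]), xdim = d)
}
.gapBwd <- function(dout, cache) {
  d <- cache$xdim
  dx <- rep(as.vector(dout), each = d[1] * d[2]) / (d[1] * d[2])
  dim(dx) <- d
  dx
}

# broadcast an (N, C) matrix over the spatial dims of an (H,W,N,C) array
.expandNC <- function(m, H, W) {
  out <- rep(as.vector(m), each = H * W)
  dim(out) <- c(H, W, nrow(m), ncol(m))
  out
}

.fcFwd <- function(x, W, b) list(out = x %*% W + rep(b, each = nrow(x)), x = x)
.fcBwd <- function(dout, cache, W)
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))

# row-wise softmax
.softmaxRows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}
# backward of row softmax: dS = P * (dP - rowSums(dP * P))
.softmaxRowsBwd <- function(dP, P) P * (dP - rowSums(dP * P))

# layer norm over the last (feature) dim of a (T x C) matrix
.lnFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(out = out, xhat = xhat, inv = inv)
}
.lnBwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dy <- dout * rep(g, each = nrow(dout))
  dx <- cache$inv * (dy - rowMeans(dy) - xhat * rowMeans(dy * xhat))
  list(dx = dx, dg = dg, db = db)
}

.geluFwd <- function(x) list(out = x * pnorm(x), x = x)
.geluBwd <- function(dout, cache)
  dout * (pnorm(cache$x) + cache$x * dnorm(cache$x))

#' @importFrom stats pnorm dnorm
NULL
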