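# The improved U-Net family.
#
# Encoder: `depth` levels of two 3x3 same-padded convolutions with ReLU,
# 2x2 max-pooling between levels; channels double per level.  Decoder: 2x2
# transposed convolutions halving channels, concatenation with the skip
# path, two 3x3 convolutions with ReLU.  Each level's skip path (the
# bottleneck path at the coarsest level) is routed through its configured
# module: plain pass-through, selective-kernel convolution, or transformer
# encoder block.  A final 1x1 convolution maps to class scores.

.bottleneckWidth <- function(C, spec)
  max(as.integer(C) %/% spec@reductionRatio, spec@minBottleneck)

# ---- selective-kernel module -------------------------------------------

#' Initialize selective-kernel module parameters
#'
#' @param channels feature-map channels C.
#' @param spec a \linkS4class{SKConvSpec}.
#' @param seed integer.
#' @return Named list of parameter arrays (per-branch convolutions, fuse
#'   bottleneck, per-branch score heads).
#' @export
skConvParams <- function(channels, spec = skConvSpec(), seed = 1L) {
  C <- as.integer(channels)
  d <- .bottleneckWidth(C, spec)
  .withSeed(seed, {
    p <- list()
    for (m in seq_along(spec@kernelSizes)) {
      k <- spec@kernelSizes[m]
      p[[paste0("branch", m, "_W")]] <-
        array(rnorm(k * k * C * C, sd = sqrt(2 / (k * k * C))), c(k, k, C, C))
      p[[paste0("branch", m, "_b")]] <- numeric(C)
    }
    p$fc1_W <- matrix(rnorm(C * d, sd = sqrt(2 / C)), C, d)
    p$fc1_b <- numeric(d)
    for (m in seq_along(spec@kernelSizes)) {
      p[[paste0("head", m, "_W")]] <-
        matrix(rnorm(d * C, sd = sqrt(2 / d)), d, C)
      p[[paste0("head", m, "_b")]] <- numeric(C)
    }
    p
  })
}

.skFwd <- function(x, spec, p, key = NULL) {
  d <- dim(x)
  M <- length(spec@kernelSizes)
  convs <- vector("list", M)
  U <- NULL
  for (m in seq_len(M)) {
    convs[[m]] <- .convFwd(x, p[[paste0("branch", m, "_W")]],
                           p[[paste0("branch", m, "_b")]],
                           key = if (is.null(key)) NULL else paste0(key, "b", m))
    U <- if (is.null(U)) convs[[m]]$out else U + convs[[m]]$out
  }
  gap <- .gapFwd(U)
  fc1 <- .fcFwd(gap$out, p$fc1_W, p$fc1_b)
  zr <- .reluFwd(fc1$out)
  E <- lapply(seq_len(M), function(m)
    .fcFwd(zr$out, p[[paste0("head", m, "_W")]], p[[paste0("head", m, "_b")]]))
  # per-(sample, channel) softmax across branches
  mx <- Reduce(pmax, lapply(E, `[[`, "out"))
  ex <- lapply(E, function(e) exp(e$out - mx))
  tot <- Reduce(`+`, ex)
  A <- lapply(ex, function(e) e / tot)
  out <- array(0, d)
  for (m in seq_len(M))
    out <- out + .expandNC(A[[m]], d[1], d[2]) * convs[[m]]$out
  list(out = out, convs = convs, gap = gap, fc1 = fc1, zr = zr, E = E, A = A,
       xdim = d)
}

.skBwd <- function(dout, cache, spec, p, pfx = "") {
  d <- cache$xdim
  M <- length(spec@kernelSizes)
  HW <- d[1] * d[2]
  g <- list()
  dU <- array(0, d)
  dUm <- vector("list", M)
  dA <- vector("list", M)
  for (m in seq_len(M)) {
    dUm[[m]] <- .expandNC(cache$A[[m]], d[1], d[2]) * dout
    dA[[m]] <- matrix(colSums(matrix(dout * cache$convs[[m]]$out, HW)),
                      d[3], d[4])
  }
  # softmax (over branches) backward per (n, c)
  s0 <- Reduce(`+`, lapply(seq_len(M), function(m) cache$A[[m]] * dA[[m]]))
  dz <- 0
  for (m in seq_len(M)) {
    dE <- cache$A[[m]] * (dA[[m]] - s0)
    fb <- .fcBwd(dE, cache$E[[m]], p[[paste0("head", m, "_W")]])
    g[[paste0(pfx, "head", m, "_W")]] <- fb$dW
    g[[paste0(pfx, "head", m, "_b")]] <- fb$db
    dz <- dz + fb$dx
  }
  dpre <- .reluBwd(dz, cache$zr)
  fb <- .fcBwd(dpre, cache$fc1, p$fc1_W)
  g[[paste0(pfx, "fc1_W")]] <- fb$dW
  g[[paste0(pfx, "fc1_b")]] <- fb$db
  dU <- .gapBwd(fb$dx, cache$gap)
  dx <- array(0, d)
  for (m in seq_len(M)) {
    cb <- .convBwd(dUm[[m]] + dU, cache$convs[[m]], p[[paste0("branch", m, "_W")]])
    g[[paste0(pfx, "branch", m, "_W")]] <- cb$dW
    g[[paste0(pfx, "branch", m, "_b")]] <- cb$db
    dx <- dx + cb$dx
  }
  list(dx = dx, grads = g)
}

#' Selective-kernel skip-module forward pass
#'
#' Split: one same-padded convolution per kernel size; Fuse: element-wise
#' branch sum, global average pool, bottleneck transform and per-branch
#' score heads; Select: per-channel softmax across branches weighting the
#' branch outputs.  Output shape equals input shape, and for every
#' (sample, channel) the selection weights are nonnegative and sum to 1.
#'
#' @param features (H, W, C) or (H, W, N, C) numeric array.
#' @param spec a \linkS4class{SKConvSpec}.
#' @param params parameter list from \code{\link{skConvParams}}.
#' @param withWeights also return the selection-weight arrays.
#' @return The transformed feature map (same shape), or, with
#'   \code{withWeights = TRUE}, a list \code{(out, weights)} where
#'   \code{weights} is an N x C x branches array.
#' @export
skConvForward <- function(features, spec = skConvSpec(), params,
                          withWeights = FALSE) {
  x <- features
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x)[1], dim(x)[2], 1L, dim(x)[3])
  if (dim(x)[4] != nrow(params$fc1_W))
    stop("channel mismatch between params and input")
  r <- .skFwd(x, spec, params)
  out <- r$out
  if (squeeze) dim(out) <- dim(features)
  if (!withWeights) return(out)
  W <- array(unlist(r$A), c(dim(x)[3], dim(x)[4], length(r$A)))
  list(out = out, weights = W)
}

# ---- transformer encoder module ----------------------------------------

#' Initialize transformer-encoder module parameters
#'
#' Token width is \code{channels * patchSize^2}; it must be divisible by
#' \code{numHeads}.
#'
#' @param side feature-map side in pixels (the map is square).
#' @param channels feature-map channels.
#' @param spec a \linkS4class{TEBSpec}.
#' @param seed integer.
#' @return Named list with learned position terms and per-block attention
#'   and feed-forward parameters.
#' @export
tebParams <- function(side, channels, spec = tebSpec(), seed = 1L) {
  p <- spec@patchSize
  if (side %% p != 0) stop("patchSize must divide the feature-map side")
  E <- as.integer(channels * p * p)
  if (E %% spec@numHeads != 0)
    stop("embedding width not divisible by numHeads")
  TT <- (side %/% p)^2
  Eh <- max(1L, round(spec@mlpRatio * E))
  .withSeed(seed, {
    pr <- list(pos = matrix(rnorm(TT * E, sd = 0.02), TT, E))
    for (b in seq_len(spec@depth)) {
      pfx <- paste0("b", b, "_")
      pr[[paste0(pfx, "ln1_g")]] <- rep(1, E)
      pr[[paste0(pfx, "ln1_b")]] <- numeric(E)
      for (nm in c("Wq", "Wk", "Wv", "Wo"))
        pr[[paste0(pfx, nm)]] <- matrix(rnorm(E * E, sd = sqrt(1 / E)), E, E)
      for (nm in c("bq", "bk", "bv", "bo"))
        pr[[paste0(pfx, nm)]] <- numeric(E)
      pr[[paste0(pfx, "ln2_g")]] <- rep(1, E)
      pr[[paste0(pfx, "ln2_b")]] <- numeric(E)
      pr[[paste0(pfx, "W1")]] <- matrix(rnorm(E * Eh, sd = sqrt(2 / E)), E, Eh)
      pr[[paste0(pfx, "b1")]] <- numeric(Eh)
      pr[[paste0(pfx, "W2")]] <- matrix(rnorm(Eh * E, sd = sqrt(2 / Eh)), Eh, E)
      pr[[paste0(pfx, "b2")]] <- numeric(E)
    }
    pr
  })
}

# tokens <-> map; patch pixels are flattened (row, col, channel) order
.toTokens <- function(xn, p) {
  # xn: (H, W, C) single sample
  d <- dim(xn)
  if (p == 1L) return(matrix(xn, d[1] * d[2], d[3]))
  Hb <- d[1] %/% p
  idx <- array(seq_len(d[1] * d[2] * d[3]), d)
  tok <- matrix(0, Hb * Hb, p * p * d[3])
  t <- 1L
  for (bj in seq_len(Hb)) for (bi in seq_len(Hb)) {
    sel <- idx[(bi - 1L) * p + seq_len(p), (bj - 1L) * p + seq_len(p), ]
    tok[t, ] <- xn[sel]
    t <- t + 1L
  }
  tok
}

.fromTokens <- function(tok, side, C, p) {
  if (p == 1L) { out <- array(tok, c(side, side, C)); return(out) }
  Hb <- side %/% p
  out <- array(0, c(side, side, C))
  idx <- array(seq_len(side * side * C), c(side, side, C))
  t <- 1L
  for (bj in seq_len(Hb)) for (bi in seq_len(Hb)) {
    sel <- idx[(bi - 1L) * p + seq_len(p), (bj - 1L) * p + seq_len(p), ]
    out[sel] <- tok[t, ]
    t <- t + 1L
  }
  out
}

# one encoder block forward on a (T x E) token matrix
.tebBlockFwd <- function(X, pr, pfx, nHeads) {
  E <- ncol(X)
  dh <- E %/% nHeads
  ln1 <- .lnFwd(X, pr[[paste0(pfx, "ln1_g")]], pr[[paste0(pfx, "ln1_b")]])
  Q <- .fcFwd(ln1$out, pr[[paste0(pfx, "Wq")]], pr[[paste0(pfx, "bq")]])
  K <- .fcFwd(ln1$out, pr[[paste0(pfx, "Wk")]], pr[[paste0(pfx, "bk")]])
  V <- .fcFwd(ln1$out, pr[[paste0(pfx, "Wv")]], pr[[paste0(pfx, "bv")]])
  heads <- vector("list", nHeads)
  O <- matrix(0, nrow(X), E)
  for (h in seq_len(nHeads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    S <- tcrossprod(Q$out[, cols, drop = FALSE], K$out[, cols, drop = FALSE]) / sqrt(dh)
    P <- .softmaxRows(S)
    O[, cols] <- P %*% V$out[, cols, drop = FALSE]
    heads[[h]] <- list(P = P, cols = cols)
  }
  proj <- .fcFwd(O, pr[[paste0(pfx, "Wo")]], pr[[paste0(pfx, "bo")]])
  X1 <- X + proj$out
  ln2 <- .lnFwd(X1, pr[[paste0(pfx, "ln2_g")]], pr[[paste0(pfx, "ln2_b")]])
  f1 <- .fcFwd(ln2$out, pr[[paste0(pfx, "W1")]], pr[[paste0(pfx, "b1")]])
  act <- .geluFwd(f1$out)
  f2 <- .fcFwd(act$out, pr[[paste0(pfx, "W2")]], pr[[paste0(pfx, "b2")]])
  X2 <- X1 + f2$out
  list(out = X2, ln1 = ln1, Q = Q, K = K, V = V, heads = heads, O = O,
       proj = proj, X1 = X1, ln2 = ln2, f1 = f1, act = act, f2 = f2, dh = dh)
}

.tebBlockBwd <- function(dX2, cache, pr, pfx, acc) {
  gadd <- function(nm, v) acc[[nm]] <- if (is.null(acc[[nm]])) v else acc[[nm]] + v
  f2b <- .fcBwd(dX2, cache$f2, pr[[paste0(pfx, "W2")]])
  gadd(paste0(pfx, "W2"), f2b$dW); gadd(paste0(pfx, "b2"), f2b$db)
  dact <- .geluBwd(f2b$dx, cache$act)
  f1b <- .fcBwd(dact, cache$f1, pr[[paste0(pfx, "W1")]])
  gadd(paste0(pfx, "W1"), f1b$dW); gadd(paste0(pfx, "b1"), f1b$db)
  ln2b <- .lnBwd(f1b$dx, cache$ln2, pr[[paste0(pfx, "ln2_g")]])
  gadd(paste0(pfx, "ln2_g"), ln2b$dg); gadd(paste0(pfx, "ln2_b"), ln2b$db)
  dX1 <- dX2 + ln2b$dx
  prb <- .fcBwd(dX1, cache$proj, pr[[paste0(pfx, "Wo")]])
  gadd(paste0(pfx, "Wo"), prb$dW); gadd(paste0(pfx, "bo"), prb$db)
  dO <- prb$dx
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- matrix(0, nrow(dO), ncol(dO))
  dV <- matrix(0, nrow(dO), ncol(dO))
  for (h in cache$heads) {
    cols <- h$cols
    P <- h$P
    dOh <- dO[, cols, drop = FALSE]
    dP <- tcrossprod(dOh, cache$V$out[, cols, drop = FALSE])
    dV[, cols] <- crossprod(P, dOh)
    dS <- .softmaxRowsBwd(dP, P) / sqrt(cache$dh)
    dQ[, cols] <- dS %*% cache$K$out[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q$out[, cols, drop = FALSE])
  }
  qb <- .fcBwd(dQ, cache$Q, pr[[paste0(pfx, "Wq")]])
  kb <- .fcBwd(dK, cache$K, pr[[paste0(pfx, "Wk")]])
  vb <- .fcBwd(dV, cache$V, pr[[paste0(pfx, "Wv")]])
  gadd(paste0(pfx, "Wq"), qb$dW); gadd(paste0(pfx, "bq"), qb$db)
  gadd(paste0(pfx, "Wk"), kb$dW); gadd(paste0(pfx, "bk"), kb$db)
  gadd(paste0(pfx, "Wv"), vb$dW); gadd(paste0(pfx, "bv"), vb$db)
  dln1 <- qb$dx + kb$dx + vb$dx
  ln1b <- .lnBwd(dln1, cache$ln1, pr[[paste0(pfx, "ln1_g")]])
  gadd(paste0(pfx, "ln1_g"), ln1b$dg); gadd(paste0(pfx, "ln1_b"), ln1b$db)
  dX1 + ln1b$dx
}

.tebFwd <- function(x, spec, pr) {
  d <- dim(x)
  if (d[1] != d[2]) stop("transformer skip module expects a square map")
  p <- spec@patchSize
  if (d[1] %% p != 0) stop("patchSize must divide the feature-map side")
  E <- d[4] * p * p
  if (E %% spec@numHeads != 0)
    stop("embedding width not divisible by numHeads")
  if (nrow(pr$pos) != (d[1] %/% p)^2)
    stop("feature-map size does not match the built position terms")
  out <- array(0, d)
  samples <- vector("list", d[3])
  for (n in seq_len(d[3])) {
    xn <- array(x[, , n, ], c(d[1], d[2], d[4]))
    X <- .toTokens(xn, p)
    X <- X + pr$pos
    blocks <- vector("list", spec@depth)
    for (b in seq_len(spec@depth)) {
      blocks[[b]] <- .tebBlockFwd(X, pr, paste0("b", b, "_"), spec@numHeads)
      X <- blocks[[b]]$out
    }
    out[, , n, ] <- .fromTokens(X, d[1], d[4], p)
    samples[[n]] <- blocks
  }
  list(out = out, samples = samples, xdim = d)
}

.tebBwd <- function(dout, cache, spec, pr, pfx = "") {
  d <- cache$xdim
  p <- spec@patchSize
  acc <- new.env(parent = emptyenv())
  dx <- array(0, d)
  dpos <- 0
  for (n in seq_len(d[3])) {
    dX <- .toTokens(array(dout[, , n, ], c(d[1], d[2], d[4])), p)
    blocks <- cache$samples[[n]]
    for (b in rev(seq_len(spec@depth)))
      dX <- .tebBlockBwd(dX, blocks[[b]], pr, paste0("b", b, "_"), acc)
    dpos <- dpos + dX
    dx[, , n, ] <- .fromTokens(dX, d[1], d[4], p)
  }
  g <- as.list(acc)
  names(g) <- paste0(pfx, names(g))
  g[[paste0(pfx, "pos")]] <- dpos
  list(dx = dx, grads = g)
}

#' Transformer-encoder skip-module forward pass
#'
#' Tokens are non-overlapping patches plus learned position terms; each
#' block is pre-norm multi-head self-attention with residual, then a
#' pre-norm feed-forward sublayer with residual; tokens are reassembled to
#' the input's spatial layout.  Every attention row is a probability vector.
#'
#' @param features (H, W, C) or (H, W, N, C) numeric array (square spatial).
#' @param spec a \linkS4class{TEBSpec}.
#' @param params parameter list from \code{\link{tebParams}}.
#' @param withWeights also return per-block, per-head attention matrices of
#'   the first sample.
#' @return The transformed map, or a list \code{(out, attention)}.
#' @export
tebForward <- function(features, spec = tebSpec(), params, withWeights = FALSE) {
  x <- features
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x)[1], dim(x)[2], 1L, dim(x)[3])
  r <- .tebFwd(x, spec, params)
  out <- r$out
  if (squeeze) dim(out) <- dim(features)
  if (!withWeights) return(out)
  att <- lapply(r$samples[[1]], function(bl) lapply(bl$heads, `[[`, "P"))
  list(out = out, attention = att)
}

# ---- full model ---------------------------------------------------------

.levelChannels <- function(spec) spec@baseChannels * 2L^(seq_len(spec@depth) - 1L)

#' Build a seeded model
#'
#' Instantiates all parameters of a \linkS4class{ModelSpec}.  Parameters of
#' layers common to every variant (encoder, decoder, up-convolutions, final
#' classifier) are drawn first under the master seed, and each skip module
#' under its own level-derived seed, so variants built from one seed share
#' bit-identical common-layer initializations (a controlled ablation).
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param seed integer.
#' @param imageSize input side the model will be applied to (needed to size
#'   the transformer position terms); must be divisible by
#'   \code{2^(depth-1)}.
#' @return A model object: list with \code{spec}, \code{imageSize},
#'   \code{params} (named list of arrays).
#' @export
buildModel <- function(spec, seed = 1L, imageSize = 64L) {
  validObject(spec)
  ch <- .levelChannels(spec)
  if (imageSize %% 2L^(spec@depth - 1L) != 0L)
    stop("input side must be divisible by 2^(depth-1)")
  he <- function(k, cin, cout)
    array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))), c(k, k, cin, cout))
  params <- .withSeed(.deriveSeed(seed, 1L), {
    p <- list()
    cin <- 1L
    for (l in seq_len(spec@depth)) {
      p[[paste0("enc", l, "_c1_W")]] <- he(3L, cin, ch[l])
      p[[paste0("enc", l, "_c1_b")]] <- numeric(ch[l])
      p[[paste0("enc", l, "_c2_W")]] <- he(3L, ch[l], ch[l])
      p[[paste0("enc", l, "_c2_b")]] <- numeric(ch[l])
      cin <- ch[l]
    }
    for (l in rev(seq_len(spec@depth - 1L))) {
      p[[paste0("up", l, "_W")]] <-
        array(rnorm(4L * ch[l + 1L] * ch[l], sd = sqrt(2 / (4 * ch[l + 1L]))),
              c(2L, 2L, ch[l + 1L], ch[l]))
      p[[paste0("up", l, "_b")]] <- numeric(ch[l])
      p[[paste0("dec", l, "_c1_W")]] <- he(3L, 2L * ch[l], ch[l])
      p[[paste0("dec", l, "_c1_b")]] <- numeric(ch[l])
      p[[paste0("dec", l, "_c2_W")]] <- he(3L, ch[l], ch[l])
      p[[paste0("dec", l, "_c2_b")]] <- numeric(ch[l])
    }
    p[["final_W"]] <- he(1L, ch[1L], spec@numClasses)
    p[["final_b"]] <- numeric(spec@numClasses)
    p
  })
  for (l in seq_len(spec@depth)) {
    mod <- spec@skipModules[l]
    if (mod == "plain") next
    side <- imageSize %/% 2L^(l - 1L)
    mseed <- .deriveSeed(seed, 100L + l)
    mp <- if (mod == "skconv") skConvParams(ch[l], spec@skSpec, mseed)
          else tebParams(side, ch[l], spec@tebSpec, mseed)
    names(mp) <- paste0("skip", l, "_", names(mp))
    params <- c(params, mp)
  }
  list(spec = spec, imageSize = as.integer(imageSize), params = params)
}

#' Total parameter count of a model (or parameter list)
#' @param model a model from \code{\link{buildModel}}, or a bare parameter
#'   list.
#' @return integer count.
#' @export
countParams <- function(model) {
  p <- if (is.list(model) && !is.null(model$params)) model$params else model
  sum(vapply(p, length, integer(1)))
}

.modelForward <- function(model, x) {
  spec <- model$spec
  p <- model$params
  d <- dim(x)
  if (d[1] %% 2L^(spec@depth - 1L) != 0L || d[2] %% 2L^(spec@depth - 1L) != 0L)
    stop("input side must be divisible by 2^(depth-1)")
  cache <- list(enc = vector("list", spec@depth),
                skip = vector("list", spec@depth),
                dec = vector("list", spec@depth))
  feats <- vector("list", spec@depth)
  h <- x
  for (l in seq_len(spec@depth)) {
    c1 <- .convFwd(h, p[[paste0("enc", l, "_c1_W")]], p[[paste0("enc", l, "_c1_b")]],
                   key = paste0("enc", l, "c1"))
    r1 <- .reluFwd(c1$out)
    c2 <- .convFwd(r1$out, p[[paste0("enc", l, "_c2_W")]], p[[paste0("enc", l, "_c2_b")]],
                   key = paste0("enc", l, "c2"))
    r2 <- .reluFwd(c2$out)
    feats[[l]] <- r2$out
    pool <- if (l < spec@depth) .poolFwd(r2$out) else NULL
    cache$enc[[l]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, pool = pool)
    h <- if (l < spec@depth) pool$out else r2$out
  }
  skips <- vector("list", spec@depth)
  for (l in seq_len(spec@depth)) {
    mod <- spec@skipModules[l]
    if (mod == "plain") { skips[[l]] <- feats[[l]]; next }
    pl <- p[grep(paste0("^skip", l, "_"), names(p))]
    names(pl) <- sub(paste0("^skip", l, "_"), "", names(pl))
    if (mod == "skconv") {
      sk <- .skFwd(feats[[l]], spec@skSpec, pl, key = paste0("skip", l))
      cache$skip[[l]] <- sk
      skips[[l]] <- sk$out
    } else {
      tb <- .tebFwd(feats[[l]], spec@tebSpec, pl)
      cache$skip[[l]] <- tb
      skips[[l]] <- tb$out
    }
  }
  dpath <- skips[[spec@depth]]
  for (l in rev(seq_len(spec@depth - 1L))) {
    up <- .upconvFwd(dpath, p[[paste0("up", l, "_W")]], p[[paste0("up", l, "_b")]])
    cat <- .concatC(skips[[l]], up$out)
    c1 <- .convFwd(cat, p[[paste0("dec", l, "_c1_W")]], p[[paste0("dec", l, "_c1_b")]],
                   key = paste0("dec", l, "c1"))
    r1 <- .reluFwd(c1$out)
    c2 <- .convFwd(r1$out, p[[paste0("dec", l, "_c2_W")]], p[[paste0("dec", l, "_c2_b")]],
                   key = paste0("dec", l, "c2"))
    r2 <- .reluFwd(c2$out)
    cache$dec[[l]] <- list(up = up, c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                           skipC = dim(skips[[l]])[4])
    dpath <- r2$out
  }
  fin <- .convFwd(dpath, p[["final_W"]], p[["final_b"]])
  cache$final <- fin
  list(scores = fin$out, cache = cache)
}

.modelBackward <- function(model, cache, dscores) {
  spec <- model$spec
  p <- model$params
  g <- list()
  fb <- .convBwd(dscores, cache$final, p[["final_W"]])
  g[["final_W"]] <- fb$dW; g[["final_b"]] <- fb$db
  ddec <- fb$dx
  dskips <- vector("list", spec@depth)
  for (l in seq_len(spec@depth - 1L)) {
    dc <- cache$dec[[l]]
    d2 <- .reluBwd(ddec, dc$r2)
    c2b <- .convBwd(d2, dc$c2, p[[paste0("dec", l, "_c2_W")]])
    g[[paste0("dec", l, "_c2_W")]] <- c2b$dW
    g[[paste0("dec", l, "_c2_b")]] <- c2b$db
    d1 <- .reluBwd(c2b$dx, dc$r1)
    c1b <- .convBwd(d1, dc$c1, p[[paste0("dec", l, "_c1_W")]])
    g[[paste0("dec", l, "_c1_W")]] <- c1b$dW
    g[[paste0("dec", l, "_c1_b")]] <- c1b$db
    sp <- .splitC(c1b$dx, dc$skipC)
    dskips[[l]] <- sp$a
    ub <- .upconvBwd(sp$b, dc$up, p[[paste0("up", l, "_W")]])
    g[[paste0("up", l, "_W")]] <- ub$dW
    g[[paste0("up", l, "_b")]] <- ub$db
    ddec <- ub$dx       # gradient w.r.t. the level-(l+1) decoder-path output
  }
  dskips[[spec@depth]] <- ddec
  denc <- vector("list", spec@depth)   # gradient arriving at each feat[[l]]
  for (l in seq_len(spec@depth)) {
    mod <- spec@skipModules[l]
    if (mod == "plain") { denc[[l]] <- dskips[[l]]; next }
    pl <- p[grep(paste0("^skip", l, "_"), names(p))]
    names(pl) <- sub(paste0("^skip", l, "_"), "", names(pl))
    mb <- if (mod == "skconv")
      .skBwd(dskips[[l]], cache$skip[[l]], spec@skSpec, pl, paste0("skip", l, "_"))
    else
      .tebBwd(dskips[[l]], cache$skip[[l]], spec@tebSpec, pl, paste0("skip", l, "_"))
    g <- c(g, mb$grads)
    denc[[l]] <- mb$dx
  }
  dh <- NULL
  for (l in rev(seq_len(spec@depth))) {
    ec <- cache$enc[[l]]
    dfeat <- denc[[l]]
    if (l < spec@depth) dfeat <- dfeat + .poolBwd(dh, ec$pool)
    d2 <- .reluBwd(dfeat, ec$r2)
    c2b <- .convBwd(d2, ec$c2, p[[paste0("enc", l, "_c2_W")]])
    g[[paste0("enc", l, "_c2_W")]] <- c2b$dW
    g[[paste0("enc", l, "_c2_b")]] <- c2b$db
    d1 <- .reluBwd(c2b$dx, ec$r1)
    c1b <- .convBwd(d1, ec$c1, p[[paste0("enc", l, "_c1_W")]])
    g[[paste0("enc", l, "_c1_W")]] <- c1b$dW
    g[[paste0("enc", l, "_c1_b")]] <- c1b$db
    dh <- c1b$dx
  }
  g
}
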