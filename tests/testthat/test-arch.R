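# Network family: selective-kernel and transformer skip modules against
# scalar-arithmetic oracles, shape/normalization contracts, seeded builds
# and the controlled-ablation parameter sharing.

test_that("equal score heads give uniform selection weights and the branch mean", {
  spec <- skConvSpec(kernelSizes = c(1L, 3L, 5L, 7L), reductionRatio = 2L,
                     minBottleneck = 2L)
  C <- 3L
  p <- skConvParams(C, spec, seed = 2)
  shared <- p$head1_W
  sharedB <- p$head1_b
  for (m in 1:4) {
    p[[paste0("head", m, "_W")]] <- shared
    p[[paste0("head", m, "_b")]] <- sharedB
  }
  set.seed(1)
  x <- array(rnorm(8 * 8 * C), c(8, 8, C))
  r <- skConvForward(x, spec, p, withWeights = TRUE)
  expect_equal(max(abs(r$weights - 0.25)), 0, tolerance = 1e-12)
  # output equals the plain mean of the four branch convolutions
  manual <- 0
  for (m in 1:4) {
    bm <- 0 * x
    W <- p[[paste0("branch", m, "_W")]]
    for (co in seq_len(C)) {
      acc <- matrix(p[[paste0("branch", m, "_b")]][co], 8, 8)
      for (ci in seq_len(C))
        acc <- acc + oracleConv2(x[, , ci], W[, , ci, co])
      bm[, , co] <- acc
    }
    manual <- manual + bm / 4
  }
  expect_equal(r$out, manual, tolerance = 1e-10)
})

test_that("a single-kernel spec passes its branch through with weight 1", {
  spec <- skConvSpec(kernelSizes = 3L, reductionRatio = 2L, minBottleneck = 2L)
  p <- skConvParams(2L, spec, seed = 5)
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  r <- skConvForward(x, spec, p, withWeights = TRUE)
  expect_equal(unique(as.vector(r$weights)), 1)
  manual <- 0 * x
  for (co in 1:2) {
    acc <- matrix(p$branch1_b[co], 6, 6)
    for (ci in 1:2) acc <- acc + oracleConv2(x[, , ci], p$branch1_W[, , ci, co])
    manual[, , co] <- acc
  }
  expect_equal(r$out, manual, tolerance = 1e-10)
})

test_that("1-channel split/fuse/select equals a scalar-arithmetic evaluation", {
  spec <- skConvSpec(kernelSizes = c(1L, 3L), reductionRatio = 1L,
                     minBottleneck = 1L)
  # hand-set small-integer parameters (bottleneck width 1)
  p <- list(branch1_W = array(2, c(1, 1, 1, 1)), branch1_b = 1,
            branch2_W = array(matrix(c(0, 1, 0, 1, -1, 1, 0, 1, 0), 3, 3),
                              c(3, 3, 1, 1)), branch2_b = 0,
            fc1_W = matrix(1, 1, 1), fc1_b = 0,
            head1_W = matrix(2, 1, 1), head1_b = 0,
            head2_W = matrix(1, 1, 1), head2_b = 1)
  x <- matrix(c(1, 2, 0, 3, 1, 1, 0, 2, 1), 3, 3)
  dim(x) <- c(3, 3, 1)
  out <- skConvForward(x, spec, p)
  # scalar oracle
  u1 <- 2 * x[, , 1] + 1
  u2 <- oracleConv2(x[, , 1], matrix(c(0, 1, 0, 1, -1, 1, 0, 1, 0), 3, 3))
  s <- mean(u1 + u2)
  z <- max(0, s)
  e1 <- 2 * z; e2 <- z + 1
  a1 <- exp(e1) / (exp(e1) + exp(e2))
  want <- a1 * u1 + (1 - a1) * u2
  expect_equal(out[, , 1], want, tolerance = 1e-12)
})

test_that("selection weights are a probability vector on random inputs", {
  spec <- skConvSpec()
  p <- skConvParams(4L, spec, seed = 9)
  set.seed(7)
  x <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  r <- skConvForward(x, spec, p, withWeights = TRUE)
  expect_identical(dim(r$out), dim(x))
  expect_true(all(r$weights >= 0))
  sums <- apply(r$weights, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-5)
})

test_that("forced-uniform attention adds one shared mean-token vector", {
  spec <- tebSpec(numHeads = 2L, mlpRatio = 2, depth = 1L, patchSize = 1L)
  C <- 4L
  p <- tebParams(4L, C, spec, seed = 3)
  p$pos <- 0 * p$pos
  p$b1_Wq <- 0 * p$b1_Wq          # zero queries -> uniform attention rows
  p$b1_W2 <- 0 * p$b1_W2          # feed-forward sublayer contributes nothing
  p$b1_b2 <- 0 * p$b1_b2
  set.seed(4)
  x <- array(rnorm(4 * 4 * C), c(4, 4, C))
  r <- tebForward(x, spec, p, withWeights = TRUE)
  for (P in r$attention[[1]]) {
    expect_equal(max(abs(P - 1 / nrow(P))), 0, tolerance = 1e-12)
  }
  delta <- r$out - x
  dm <- matrix(delta, 16, C)
  # the same additive vector at every position
  expect_equal(max(abs(sweep(dm, 2, dm[1, ]))), 0, tolerance = 1e-10)
})

test_that("a single token attends only to itself", {
  spec <- tebSpec(numHeads = 1L, mlpRatio = 2, depth = 1L, patchSize = 1L)
  C <- 3L
  p <- tebParams(1L, C, spec, seed = 6)
  p$pos <- 0 * p$pos
  x <- array(c(0.3, -1.2, 0.8), c(1, 1, C))
  r <- tebForward(x, spec, p, withWeights = TRUE)
  expect_equal(as.vector(r$attention[[1]][[1]]), 1)
  # attention output is exactly the value projection routed through Wo
  ln <- (as.vector(x) - mean(x)) / sqrt(var(as.vector(x)) * (C - 1) / C + 1e-5)
  v <- ln %*% p$b1_Wv + p$b1_bv
  o <- v %*% p$b1_Wo + p$b1_bo
  x1 <- as.vector(x) + as.vector(o)
  ln2 <- (x1 - mean(x1)) / sqrt(var(x1) * (C - 1) / C + 1e-5)
  h <- ln2 %*% p$b1_W1 + p$b1_b1
  h <- h * pnorm(h)
  want <- x1 + as.vector(h %*% p$b1_W2 + p$b1_b2)
  expect_equal(as.vector(r$out), want, tolerance = 1e-10)
})

test_that("2x2 single-head attention matches a scalar QK^T/sqrt(d) evaluation", {
  spec <- tebSpec(numHeads = 1L, mlpRatio = 1, depth = 1L, patchSize = 1L)
  C <- 2L
  p <- tebParams(2L, C, spec, seed = 1)
  # hand-set projections; neutralize norm and feed-forward for the oracle
  p$pos <- 0 * p$pos
  p$b1_ln1_g <- rep(1, C); p$b1_ln1_b <- rep(0, C)
  p$b1_Wq <- matrix(c(1, 0, 0, 1), 2, 2); p$b1_bq <- c(0, 0)
  p$b1_Wk <- matrix(c(0, 1, 1, 0), 2, 2); p$b1_bk <- c(0, 0)
  p$b1_Wv <- matrix(c(1, 1, 0, 1), 2, 2); p$b1_bv <- c(0, 0)
  p$b1_Wo <- diag(2); p$b1_bo <- c(0, 0)
  p$b1_W2 <- matrix(0, 2, 2); p$b1_b2 <- c(0, 0)
  x <- array(c(1, 0, -1, 2, 0.5, -0.5, 1.5, 0), c(2, 2, C))
  out <- tebForward(x, spec, p)
  X <- matrix(x, 4, C)
  LN <- t(apply(X, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  Q <- LN %*% p$b1_Wq; K <- LN %*% p$b1_Wk; V <- LN %*% p$b1_Wv
  S <- Q %*% t(K) / sqrt(2)
  P <- exp(S) / rowSums(exp(S))
  want <- X + (P %*% V) %*% p$b1_Wo
  expect_equal(matrix(out, 4, C), want, tolerance = 1e-10)
})

test_that("attention rows are probability vectors and shapes are preserved", {
  spec <- tebSpec(numHeads = 4L, mlpRatio = 4, depth = 2L, patchSize = 1L)
  p <- tebParams(4L, 8L, spec, seed = 11)
  set.seed(12)
  x <- array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8))
  r <- tebForward(x, spec, p, withWeights = TRUE)
  expect_identical(dim(r$out), dim(x))
  for (bl in r$attention) for (P in bl) {
    expect_true(all(P >= 0))
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-5)
  }
})

test_that("patch tokenization errors on indivisible sides and supports p > 1", {
  spec <- tebSpec(numHeads = 2L, mlpRatio = 2, depth = 1L, patchSize = 2L)
  p <- tebParams(6L, 1L, spec, seed = 2)
  set.seed(3)
  x <- array(rnorm(6 * 6), c(6, 6, 1))
  out <- tebForward(x, spec, p)
  expect_identical(dim(out), dim(x))
  bad <- array(rnorm(5 * 5), c(5, 5, 1))
  expect_error(tebForward(bad, spec, tebParams(5L, 1L, spec, seed = 2)),
               "patchSize")
  expect_error(tebSpec(numHeads = 0L), "numHeads")
})

test_that("seeded builds are bit-identical and respect the variant layouts", {
  spec <- modelSpec(variant = "improved")
  a <- buildModel(spec, seed = 4, imageSize = 64)
  b <- buildModel(spec, seed = 4, imageSize = 64)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$enc1_c1_W,
                         buildModel(spec, seed = 5, imageSize = 64)$params$enc1_c1_W))
  expect_identical(variantSkipLayout("base"), rep("plain", 5))
  expect_identical(variantSkipLayout("sk"),
                   c("skconv", "skconv", "skconv", "plain", "plain"))
  expect_identical(variantSkipLayout("teb"),
                   c("plain", "plain", "plain", "teb", "teb"))
  expect_identical(variantSkipLayout("improved"),
                   c("skconv", "skconv", "skconv", "teb", "teb"))
})

test_that("variants built from one seed share identical common parameters", {
  vs <- modelVariants(modelSpec(baseChannels = 4L))
  ms <- lapply(vs, buildModel, seed = 9, imageSize = 32)
  common <- names(ms$base$params)
  for (v in c("sk", "teb", "improved"))
    expect_identical(ms[[v]]$params[common], ms$base$params)
})

test_that("parameter count difference equals the summed skip-module sizes", {
  spec <- modelSpec(baseChannels = 4L)
  base <- buildModel(spec, seed = 2, imageSize = 32)
  skv <- modelVariants(spec)$sk
  skm <- buildModel(skv, seed = 2, imageSize = 32)
  ch <- as.integer(4 * 2^(0:2))
  wantExtra <- 0
  for (C in ch) {
    d <- max(C %/% 8L, 16L)     # reduction 8, floor 16
    perBranch <- function(k) k * k * C * C + C
    wantExtra <- wantExtra +
      sum(vapply(c(1, 3, 5, 7), perBranch, numeric(1))) +      # splits
      C * d + d +                                              # fuse bottleneck
      4L * (d * C + C)                                         # score heads
  }
  expect_equal(countParams(skm) - countParams(base), wantExtra)
})

test_that("forward pass maps a 64x64 input to a 64x64 x classes score map", {
  m <- buildModel(modelSpec(variant = "improved"), seed = 1, imageSize = 64)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  sc <- apexseg:::.modelForward(m, x)$scores
  expect_identical(dim(sc), c(64L, 64L, 1L, 4L))
  bad <- array(runif(60 * 60), c(60, 60, 1, 1))
  expect_error(apexseg:::.modelForward(m, bad), "divisible")
})

test_that("skip modules are drop-in: plain, SK and TEB outputs share the skip shape", {
  skp <- skConvParams(4L, skConvSpec(), seed = 1)
  tbp <- tebParams(8L, 4L, tebSpec(), seed = 1)
  set.seed(5)
  x <- array(rnorm(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  expect_identical(dim(skConvForward(x, skConvSpec(), skp)), dim(x))
  expect_identical(dim(tebForward(x, tebSpec(), tbp)), dim(x))
})

test_that("channel mismatch between SK params and input raises an error", {
  p <- skConvParams(4L, skConvSpec(), seed = 1)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  expect_error(skConvForward(x, skConvSpec(), p), "channel mismatch")
})

test_that("analytic gradients match finite differences on a tiny improved net", {
  spec <- tinyModelSpec()
  m <- buildModel(spec, seed = 3, imageSize = 8)
  set.seed(1)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  y <- array(sample(0:2, 64, TRUE), c(8, 8, 1))
  g <- modelGradient(m, x, y)
  eps <- 1e-5
  set.seed(42)
  for (nm in names(m$params)) {
    npar <- length(m$params[[nm]])
    for (ii in sample(npar, min(2, npar))) {
      m2 <- m
      m2$params[[nm]][ii] <- m2$params[[nm]][ii] + eps
      lp <- modelGradient(m2, x, y)$loss
      m2$params[[nm]][ii] <- m2$params[[nm]][ii] - 2 * eps
      lm_ <- modelGradient(m2, x, y)$loss
      num <- (lp - lm_) / (2 * eps)
      ana <- g$grads[[nm]][ii]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("every skip module receives nonzero gradient (no dead branches)", {
  spec <- modelSpec(baseChannels = 2L, variant = "improved",
                    skSpec = skConvSpec(reductionRatio = 2L, minBottleneck = 2L),
                    tebSpec = tebSpec(numHeads = 2L, mlpRatio = 2, depth = 1L))
  m <- buildModel(spec, seed = 8, imageSize = 32)
  set.seed(2)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2, 1))
  y <- array(sample(0:3, 32 * 32 * 2, TRUE), c(32, 32, 2))
  g <- modelGradient(m, x, y)
  for (l in 1:5) {
    nms <- grep(paste0("^skip", l, "_"), names(g$grads), value = TRUE)
    expect_gt(length(nms), 0)
    expect_true(any(vapply(nms, function(nm) any(g$grads[[nm]] != 0), logical(1))),
                info = paste("level", l))
  }
})
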