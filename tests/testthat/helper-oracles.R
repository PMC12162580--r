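# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain loops and scalar arithmetic only.

# exhaustive per-pixel confusion enumeration for one class
oracleConfusion <- function(pred, truth, classId) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] == classId
    t <- truth[i, j] == classId
    if (p && t) tp <- tp + 1L
    else if (p) fp <- fp + 1L
    else if (t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# rectangle IoU from corner arithmetic (center-form input)
oracleBoxIou <- function(a, b) {
  ca <- c(a[1] - a[3] / 2, a[2] - a[4] / 2, a[1] + a[3] / 2, a[2] + a[4] / 2)
  cb <- c(b[1] - b[3] / 2, b[2] - b[4] / 2, b[1] + b[3] / 2, b[2] + b[4] / 2)
  w <- min(ca[3], cb[3]) - max(ca[1], cb[1])
  h <- min(ca[4], cb[4]) - max(ca[2], cb[2])
  inter <- max(0, w) * max(0, h)
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# plain-loop greedy matcher: per category, detections by descending
# confidence each claim the unclaimed truth of highest IoU >= thr
oracleMatch <- function(dets, truths, thr) {
  tp <- 0L
  claimed <- rep(FALSE, nrow(truths))
  for (cat in unique(c(dets$category, truths$category))) {
    di <- which(dets$category == cat)
    di <- di[order(dets$confidence[di], decreasing = TRUE)]
    ti <- which(truths$category == cat)
    for (d in di) {
      bestIou <- -1; best <- 0L
      for (t in ti) {
        if (claimed[t]) next
        v <- oracleBoxIou(as.numeric(dets[d, c("cx", "cy", "w", "h")]),
                          as.numeric(truths[t, c("cx", "cy", "w", "h")]))
        if (v > bestIou) { bestIou <- v; best <- t }
      }
      if (best > 0L && bestIou >= thr) { claimed[best] <- TRUE; tp <- tp + 1L }
    }
  }
  c(tp = tp, fp = nrow(dets) - tp, fn = sum(!claimed))
}

# all-pairs concordance AUC (ties count 1/2)
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# direct scalar-loop same-padded 2-D convolution of a 1-channel map
oracleConv2 <- function(x, w, b = 0) {
  if (is.null(dim(w))) w <- matrix(w, sqrt(length(w)), sqrt(length(w)))
  k <- nrow(w)
  p <- (k - 1) / 2
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    acc <- b
    for (di in seq_len(k)) for (dj in seq_len(k)) {
      ii <- i + di - 1 - p
      jj <- j + dj - 1 - p
      if (ii >= 1 && ii <= nrow(x) && jj >= 1 && jj <= ncol(x))
        acc <- acc + x[ii, jj] * w[di, dj]
    }
    out[i, j] <- acc
  }
  out
}

# winding-number point-in-polygon (a different formulation from the
# package's crossing-number test)
oracleInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(vy[i] - py, vx[i] - px)
    a2 <- atan2(vy[j] - py, vx[j] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi   # ~2*pi inside, ~0 outside
}

# random box set helpers for matcher stress tests
randomBoxes <- function(n, withConf = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cats <- boxCategories()$name
  df <- data.frame(category = sample(cats, n, TRUE),
                   cx = runif(n, 0.2, 0.8), cy = runif(n, 0.2, 0.8),
                   w = runif(n, 0.05, 0.3), h = runif(n, 0.05, 0.3))
  if (withConf) df$confidence <- round(runif(n), 3)
  df
}

tinyModelSpec <- function() {
  modelSpec(depth = 3L, baseChannels = 2L, numClasses = 3L,
            skipModules = c("skconv", "teb", "plain"),
            skSpec = skConvSpec(kernelSizes = c(1L, 3L), reductionRatio = 2L,
                                minBottleneck = 2L),
            tebSpec = tebSpec(numHeads = 2L, mlpRatio = 2, depth = 1L,
                              patchSize = 1L))
}
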