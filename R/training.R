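# Seeded CPU training loop: Adam on softmax cross-entropy (optionally soft
# Dice or their sum) with per-epoch validation mIoU over the three
# foreground structures.

.sliceImage <- function(s) if (methods::is(s, "PhantomSlice")) s@image else s$image
.sliceMask <- function(s) if (methods::is(s, "PhantomSlice")) s@mask else s$mask

.stackBatch <- function(slices, idx, augOps = character(), augSeed = NULL) {
  S <- nrow(.sliceImage(slices[[idx[1]]]))
  x <- array(0, c(S, S, length(idx), 1L))
  y <- array(0L, c(S, S, length(idx)))
  for (j in seq_along(idx)) {
    im <- .sliceImage(slices[[idx[j]]])
    mk <- .sliceMask(slices[[idx[j]]])
    if (length(augOps) && !is.null(augSeed)) {
      a <- augment(im, mk, augOps, seed = .deriveSeed(augSeed, idx[j]))
      im <- a$image; mk <- a$mask
    }
    x[, , j, 1L] <- im
    y[, , j] <- mk
  }
  list(x = x, y = y)
}

# loss forward + gradient w.r.t. scores.  scores: (H,W,N,K); labels: (H,W,N)
# integer 0-based class codes.
.lossGrad <- function(scores, labels, lossName = "cross_entropy", eps = 1e-7) {
  K <- dim(scores)[4]
  n <- prod(dim(scores)[1:3])
  P <- .softmaxRows(matrix(scores, ncol = K))
  iy <- cbind(seq_len(n), as.vector(labels) + 1L)
  loss <- 0
  dP <- NULL
  dscores <- matrix(0, n, K)
  if (lossName %in% c("cross_entropy", "combined")) {
    loss <- loss - mean(log(pmax(P[iy], 1e-12)))
    Y <- matrix(0, n, K)
    Y[iy] <- 1
    dscores <- dscores + (P - Y) / n
  }
  if (lossName %in% c("dice", "combined")) {
    Y <- matrix(0, n, K)
    Y[iy] <- 1
    num <- 2 * colSums(P * Y)
    den <- colSums(P) + colSums(Y)
    loss <- loss + mean(1 - (num + eps) / (den + eps))
    dPd <- -(sweep(Y, 2, 2 * (den + eps), "*") -
               matrix(num + eps, n, K, byrow = TRUE)) /
      matrix((den + eps)^2, n, K, byrow = TRUE) / K
    dscores <- dscores + .softmaxRowsBwd(dPd, P)
  }
  dim(dscores) <- dim(scores)
  list(loss = loss, dscores = dscores)
}

#' Loss and parameter gradient on a batch
#'
#' Runs one forward/backward pass of a model on a stacked batch and returns
#' the loss with the full named gradient list (no parameter update).
#'
#' @param model model from \code{\link{buildModel}}.
#' @param images numeric array (H, W, N, 1) or a single (H, W) matrix.
#' @param masks integer array (H, W, N) or matrix of 0-based class codes.
#' @param lossName \code{"cross_entropy"}, \code{"dice"} or
#'   \code{"combined"}.
#' @return list with \code{loss} and \code{grads}.
#' @export
modelGradient <- function(model, images, masks, lossName = "cross_entropy") {
  if (is.matrix(images)) dim(images) <- c(dim(images), 1L, 1L)
  if (is.matrix(masks)) dim(masks) <- c(dim(masks), 1L)
  fw <- .modelForward(model, images)
  lg <- .lossGrad(fw$scores, masks, lossName)
  grads <- .modelBackward(model, fw$cache, lg$dscores)
  list(loss = lg$loss, grads = grads)
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

#' Validation mean IoU over the foreground structures
#'
#' @param model trained model.
#' @param valSet list of slices (PhantomSlice or \code{list(image, mask)}).
#' @param includeBackground include class 0 in the mean (default FALSE).
#' @return numeric mIoU.
#' @export
validationMiou <- function(model, valSet, includeBackground = FALSE) {
  preds <- lapply(valSet, function(s) predictMask(model, .sliceImage(s)))
  truths <- lapply(valSet, .sliceMask)
  rep <- evaluateSegmentation(preds, truths,
                              numClasses = model$spec@numClasses,
                              includeBackground = includeBackground)
  rep@mIoU
}

#' Train a model variant on a phantom (or user) dataset
#'
#' Deterministic, seeded mini-batch Adam training.  The per-epoch log
#' records the mean training loss and, when a validation set is given, the
#' validation mIoU over the three foreground structures.  Identical
#' \code{(spec, dataset, config)} reproduce identical logs.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param trainSet nonempty list of slices (all images the same size).
#' @param config a \linkS4class{TrainConfig}.
#' @param valSet optional validation slices evaluated every epoch.
#' @return list with \code{model} (trained), \code{log} (data.frame with
#'   \code{epoch}, \code{loss}, \code{valMiou}), and \code{epochsRun}.
#' @export
trainModel <- function(spec, trainSet, config, valSet = NULL) {
  if (length(trainSet) == 0L) stop("empty training set")
  sizes <- vapply(trainSet, function(s) nrow(.sliceImage(s)), integer(1))
  if (length(unique(sizes)) != 1L) stop("all training images must share one size")
  S <- sizes[1]
  if (S %% 2L^(spec@depth - 1L) != 0L)
    stop("image size incompatible with model depth")
  model <- buildModel(spec, seed = config@seed, imageSize = S)
  st <- .adamInit(model$params)
  n <- length(trainSet)
  log <- data.frame(epoch = integer(), loss = numeric(), valMiou = numeric())
  if (config@checkpointEvery > 0L)
    dir.create(config@checkpointDir, showWarnings = FALSE, recursive = TRUE)
  epochsRun <- 0L
  for (ep in seq_len(config@epochs)) {
    perm <- .withSeed(.deriveSeed(config@seed, 7000L + ep), sample.int(n))
    batches <- split(perm, ceiling(seq_along(perm) / config@batchSize))
    epLoss <- 0
    for (b in batches) {
      bt <- .stackBatch(trainSet, b, config@augmentationOps,
                        augSeed = .deriveSeed(config@seed, 9000L + ep))
      gl <- modelGradient(model, bt$x, bt$y, config@lossName)
      epLoss <- epLoss + gl$loss * length(b)
      if (config@learningRate > 0) {
        upd <- .adamStep(model$params, gl$grads, st, config@learningRate)
        model$params <- upd$params
        st <- upd$state
      }
    }
    vm <- if (!is.null(valSet)) validationMiou(model, valSet) else NA_real_
    log <- rbind(log, data.frame(epoch = ep, loss = epLoss / n, valMiou = vm))
    epochsRun <- ep
    if (config@checkpointEvery > 0L && ep %% config@checkpointEvery == 0L)
      saveRDS(model$params, file.path(config@checkpointDir,
                                      sprintf("epoch%03d.rds", ep)))
    if (!is.na(config@stopMiou) && !is.na(vm) && vm >= config@stopMiou) break
  }
  list(model = model, log = log, epochsRun = epochsRun)
}

#' Predict a label mask for one image
#'
#' Per-pixel argmax over the class score map; ties break toward the lower
#' class index.
#'
#' @param model model from \code{\link{buildModel}} or \code{\link{trainModel}}.
#' @param image numeric matrix, side compatible with the model depth.
#' @return integer matrix of 0-based class codes.
#' @export
predictMask <- function(model, image) {
  if (!is.matrix(image)) stop("image must be a matrix")
  x <- array(image, c(dim(image), 1L, 1L))
  sc <- .modelForward(model, x)$scores
  scoresToMask(sc[, , 1L, ])
}

#' Convert a score map to a label mask
#'
#' @param scores numeric array (H, W, K) of per-class scores.
#' @return integer matrix of 0-based argmax codes, ties toward lower index.
#' @export
scoresToMask <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}
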