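#' @title Classes for phantom generation and model specification
#' @name apexseg-classes
#' @rdname apexseg-classes
#' @description
#' S4 containers for the phantom generator configuration, a generated slice,
#' the network specifications (selective-kernel and transformer-encoder skip
#' modules, full model), the training configuration, segmentation reports and
#' ablation results.
NULL

#' PhantomConfig: synthetic slice generator settings
#'
#' Configuration of the orbital-apex phantom generator.  A phantom slice is a
#' square grayscale image in [0,1] containing, on each side, a dark air-filled
#' sphenoid sinus, a bright contrast-enhanced internal carotid artery disc
#' touching the sinus lateral border, and a thin bright optic-canal ring
#' superior-lateral to the sinus; optionally a fracture lesion (ring gap plus
#' displaced fragment) is cut into the canal.
#'
#' @slot imageSize integer, pixels per (square) side; at least 32 and even.
#' @slot intensityLevels named numeric in [0,1]: mean intensity for
#'   \code{background}, \code{OC}, \code{ICA}, \code{SS}.
#' @slot noiseSd numeric, additive Gaussian noise scale.
#' @slot textureContrast numeric in [0,1], amplitude of class-specific texture.
#' @slot textureFreq named list: per-class spatial frequency pairs
#'   (cycles/pixel) of the texture gratings.
#' @slot fractureProbLeft,fractureProbRight numeric in [0,1].
#' @slot seed integer master seed recorded with the config.
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  imageSize = "integer",
  intensityLevels = "numeric",
  noiseSd = "numeric",
  textureContrast = "numeric",
  textureFreq = "list",
  fractureProbLeft = "numeric",
  fractureProbRight = "numeric",
  seed = "integer"
))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32")
  if (object@imageSize %% 2L != 0L) msg <- c(msg, "imageSize must be even")
  need <- c("background", "OC", "ICA", "SS")
  if (!all(need %in% names(object@intensityLevels)))
    msg <- c(msg, "intensityLevels must name background, OC, ICA, SS")
  if (any(object@intensityLevels < 0 | object@intensityLevels > 1))
    msg <- c(msg, "intensity means must lie in [0,1]")
  for (p in c(object@fractureProbLeft, object@fractureProbRight))
    if (p < 0 || p > 1) msg <- c(msg, "fracture probabilities must lie in [0,1]")
  if (object@textureContrast < 0 || object@textureContrast > 1)
    msg <- c(msg, "textureContrast must lie in [0,1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' PhantomSlice: one synthetic slice with ground truth
#'
#' @slot image numeric matrix in [0,1], row-major interpretation with origin
#'   at the top-left (row 1 = top).
#' @slot mask integer matrix of the same shape; 0 = background, 1 = OC,
#'   2 = ICA, 3 = SS.
#' @slot boxes data.frame with one row per side: \code{category},
#'   \code{x0,y0,x1,y1} half-open 0-based pixel extents, plus normalized
#'   center form \code{cx,cy,w,h}.
#' @slot primitives list of the geometry primitives drawn (for independent
#'   re-rasterization).
#' @slot seedUsed integer seed the slice was drawn under.
#' @exportClass PhantomSlice
setClass("PhantomSlice", representation(
  image = "matrix",
  mask = "matrix",
  boxes = "data.frame",
  primitives = "list",
  seedUsed = "integer"
))

setValidity("PhantomSlice", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask shapes differ")
  if (nrow(object@boxes) != 2L) msg <- c(msg, "expected exactly one box per side")
  if (length(msg)) msg else TRUE
})

#' SKConvSpec: selective-kernel skip-module settings
#'
#' @slot kernelSizes integer vector of odd, strictly increasing kernel sides;
#'   default \code{c(1,3,5,7)}.
#' @slot reductionRatio integer, channel reduction of the fuse bottleneck.
#' @slot minBottleneck integer, floor on the bottleneck width.
#' @exportClass SKConvSpec
setClass("SKConvSpec", representation(
  kernelSizes = "integer",
  reductionRatio = "integer",
  minBottleneck = "integer"
))

setValidity("SKConvSpec", function(object) {
  k <- object@kernelSizes
  msg <- character()
  if (length(k) < 1L) msg <- c(msg, "need at least one kernel size")
  if (any(k %% 2L == 0L)) msg <- c(msg, "kernel sizes must be odd")
  if (length(k) > 1L && any(diff(k) <= 0L))
    msg <- c(msg, "kernel sizes must be strictly increasing")
  if (object@reductionRatio < 1L) msg <- c(msg, "reductionRatio must be >= 1")
  if (object@minBottleneck < 1L) msg <- c(msg, "minBottleneck must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TEBSpec: transformer-encoder skip-module settings
#'
#' @slot numHeads integer number of attention heads.
#' @slot mlpRatio numeric expansion factor of the feed-forward sublayer.
#' @slot depth integer number of stacked encoder blocks.
#' @slot patchSize integer pixels per token side (1 on the coarse maps).
#' @exportClass TEBSpec
setClass("TEBSpec", representation(
  numHeads = "integer",
  mlpRatio = "numeric",
  depth = "integer",
  patchSize = "integer"
))

setValidity("TEBSpec", function(object) {
  msg <- character()
  if (object@numHeads < 1L) msg <- c(msg, "numHeads must be >= 1")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@patchSize < 1L) msg <- c(msg, "patchSize must be >= 1")
  if (object@mlpRatio <= 0) msg <- c(msg, "mlpRatio must be positive")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: a U-Net variant
#'
#' Describes one member of the model family: a U-Net of \code{depth}
#' resolution levels (level 1 = full resolution) whose per-level skip
#' connection carries either a plain pass-through, a selective-kernel
#' convolution module, or a transformer encoder block.  The level-`depth`
#' entry configures the module applied to the bottleneck path.
#'
#' @slot depth integer number of resolution levels (default 5).
#' @slot baseChannels integer channels at level 1, doubling per level.
#' @slot numClasses integer output classes including background (default 4).
#' @slot skipModules character vector of length \code{depth}, each one of
#'   \code{"plain"}, \code{"skconv"}, \code{"teb"}.
#' @slot skSpec a \linkS4class{SKConvSpec}.
#' @slot tebSpec a \linkS4class{TEBSpec}.
#' @exportClass ModelSpec
setClass("ModelSpec", representation(
  depth = "integer",
  baseChannels = "integer",
  numClasses = "integer",
  skipModules = "character",
  skSpec = "SKConvSpec",
  tebSpec = "TEBSpec"
))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@numClasses < 2L) msg <- c(msg, "numClasses must be >= 2")
  if (length(object@skipModules) != object@depth)
    msg <- c(msg, "skipModules must have one entry per level")
  if (!all(object@skipModules %in% c("plain", "skconv", "teb")))
    msg <- c(msg, "skip modules must be plain, skconv or teb")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: training-loop settings
#'
#' @slot epochs,batchSize integer counts (>= 1).
#' @slot learningRate positive numeric.
#' @slot lossName one of \code{"cross_entropy"}, \code{"dice"},
#'   \code{"combined"}.
#' @slot augmentationOps character vector of augmentation op names applied
#'   (seeded) to each training slice.
#' @slot seed integer.
#' @slot checkpointEvery integer; 0 disables checkpoints.
#' @slot checkpointDir character path for checkpoints.
#' @slot stopMiou numeric; stop early once validation mIoU reaches this
#'   value (NA disables).
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  epochs = "integer",
  batchSize = "integer",
  learningRate = "numeric",
  lossName = "character",
  augmentationOps = "character",
  seed = "integer",
  checkpointEvery = "integer",
  checkpointDir = "character",
  stopMiou = "numeric"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (!object@lossName %in% c("cross_entropy", "dice", "combined"))
    msg <- c(msg, "lossName must be cross_entropy, dice or combined")
  if (length(msg)) msg else TRUE
})

#' SegReport: per-class and mean segmentation metrics
#'
#' @slot perClass numeric matrix, one row per class, columns \code{IoU} and
#'   \code{Dice}.
#' @slot mIoU,mDice numeric means over the averaged class set.
#' @slot includeBackground logical flag recorded with the report.
#' @slot k integer number of classes averaged.
#' @exportClass SegReport
setClass("SegReport", representation(
  perClass = "matrix",
  mIoU = "numeric",
  mDice = "numeric",
  includeBackground = "logical",
  k = "integer"
))

setValidity("SegReport", function(object) {
  msg <- character()
  v <- object@perClass
  if (any(v < -1e-12 | v > 1 + 1e-12)) msg <- c(msg, "metrics must lie in [0,1]")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(msg)) msg else TRUE
})

#' AblationResult: four-variant comparison table
#'
#' @slot cells numeric array variant x class x metric of held-out IoU/Dice,
#'   averaged over seeds.
#' @slot means numeric matrix variant x {mIoU, mDice, mIoU_bg, mDice_bg}.
#' @slot seeds integer vector of seeds used.
#' @slot configHash character hash of the run configuration.
#' @exportClass AblationResult
setClass("AblationResult", representation(
  cells = "array",
  means = "matrix",
  seeds = "integer",
  configHash = "character"
))

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %dx%d px, noise sd %.3g, texture %.2f\n",
              object@imageSize, object@imageSize, object@noiseSd,
              object@textureContrast))
  lv <- object@intensityLevels
  cat("  intensity:", paste(sprintf("%s=%.2f", names(lv), lv), collapse = ", "), "\n")
  cat(sprintf("  fracture prob L=%.2f R=%.2f, seed %d\n",
              object@fractureProbLeft, object@fractureProbRight, object@seed))
})

setMethod("show", "PhantomSlice", function(object) {
  cat(sprintf("PhantomSlice %dx%d (seed %d)\n", nrow(object@image),
              ncol(object@image), object@seedUsed))
  tab <- table(factor(object@mask, levels = 0:3,
                      labels = c("background", "OC", "ICA", "SS")))
  cat("  mask pixels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                              collapse = ", "), "\n")
  cat("  boxes:", paste(object@boxes$category, collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: depth %d, base %d channels, %d classes\n",
              object@depth, object@baseChannels, object@numClasses))
  cat("  skips:", paste(sprintf("L%d=%s", seq_len(object@depth),
                                object@skipModules), collapse = " "), "\n")
})

setMethod("show", "SegReport", function(object) {
  cat(sprintf("SegReport (k = %d, background %s)\n", object@k,
              if (object@includeBackground) "included" else "excluded"))
  print(round(object@perClass, 4))
  cat(sprintf("  mIoU = %.4f, mDice = %.4f\n", object@mIoU, object@mDice))
})

setMethod("show", "AblationResult", function(object) {
  cat("AblationResult over seeds:", paste(object@seeds, collapse = ", "), "\n")
  print(round(object@means, 4))
})
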