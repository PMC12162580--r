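#' Create a phantom generator configuration
#'
#' Builds a \linkS4class{PhantomConfig}.  Defaults emulate a
#' contrast-enhanced axial orbital-apex slice: the sphenoid sinus is
#' air-filled (dark), the internal carotid artery is contrast-enhanced
#' (bright), and the optic-canal wall is intermediate bone.  Each class also
#' carries a characteristic texture grating whose amplitude is
#' \code{textureContrast}.
#'
#' @param imageSize pixels per side (square, even, >= 32).
#' @param intensityLevels named numeric mean intensities in [0,1] for
#'   \code{background}, \code{OC}, \code{ICA}, \code{SS}.
#' @param noiseSd additive Gaussian noise scale.
#' @param textureContrast amplitude in [0,1] of class texture modulation.
#' @param textureFreq named list of length-2 frequency vectors (cycles/px)
#'   per class; classes absent from the list get no texture.
#' @param fractureProbLeft,fractureProbRight per-side fracture probabilities.
#' @param seed integer master seed.
#' @return A \linkS4class{PhantomConfig}.
#' @export
#' @examples
#' cfg <- phantomConfig()
#' cfg
phantomConfig <- function(imageSize = 64L,
                          intensityLevels = c(background = 0.35, OC = 0.65,
                                              ICA = 0.90, SS = 0.08),
                          noiseSd = 0.02,
                          textureContrast = 0.15,
                          textureFreq = list(OC = c(1 / 3, 1 / 3),
                                             SS = c(0.15, 0)),
                          fractureProbLeft = 0.5,
                          fractureProbRight = 0.5,
                          seed = 1L) {
  new("PhantomConfig",
      imageSize = as.integer(imageSize),
      intensityLevels = intensityLevels,
      noiseSd = as.numeric(noiseSd),
      textureContrast = as.numeric(textureContrast),
      textureFreq = textureFreq,
      fractureProbLeft = as.numeric(fractureProbLeft),
      fractureProbRight = as.numeric(fractureProbRight),
      seed = as.integer(seed))
}

#' Preset: easily separable phantom family
#'
#' Classes differ in mean intensity (the easy benchmark): low noise, visible
#' texture.
#' @param ... overrides passed to \code{\link{phantomConfig}}.
#' @return A \linkS4class{PhantomConfig}.
#' @export
easyPhantomConfig <- function(...) {
  phantomConfig(noiseSd = 0.01, textureContrast = 0.2, ...)
}

#' Preset: texture-confusable phantom family
#'
#' All three structures share one mean intensity and differ only in the
#' period of a diagonal texture grating (3, 6 and 12 px for OC, ICA, SS).
#' Telling the classes apart therefore requires integrating texture over
#' windows larger than a 3x3 kernel, which is the difficulty axis the
#' selective-kernel skip module addresses.
#' @param ... overrides passed to \code{\link{phantomConfig}}.
#' @return A \linkS4class{PhantomConfig}.
#' @export
textureConfusablePhantomConfig <- function(...) {
  phantomConfig(
    intensityLevels = c(background = 0.35, OC = 0.55, ICA = 0.55, SS = 0.55),
    noiseSd = 0.01,
    textureContrast = 0.35,
    textureFreq = list(OC = c(1 / 3, 1 / 3), ICA = c(1 / 6, 1 / 6),
                       SS = c(1 / 12, 1 / 12)),
    ...)
}

#' Selective-kernel module specification
#'
#' @param kernelSizes odd, strictly increasing kernel sides; the default
#'   \code{c(1,3,5,7)} gives the four-branch split.
#' @param reductionRatio fuse bottleneck reduction.
#' @param minBottleneck floor on the bottleneck width.
#' @return A \linkS4class{SKConvSpec}.
#' @export
skConvSpec <- function(kernelSizes = c(1L, 3L, 5L, 7L), reductionRatio = 8L,
                       minBottleneck = 16L) {
  new("SKConvSpec", kernelSizes = as.integer(kernelSizes),
      reductionRatio = as.integer(reductionRatio),
      minBottleneck = as.integer(minBottleneck))
}

#' Transformer-encoder module specification
#'
#' @param numHeads attention heads.
#' @param mlpRatio feed-forward expansion factor.
#' @param depth stacked encoder blocks.
#' @param patchSize pixels per token side.
#' @return A \linkS4class{TEBSpec}.
#' @export
tebSpec <- function(numHeads = 4L, mlpRatio = 4, depth = 2L, patchSize = 1L) {
  new("TEBSpec", numHeads = as.integer(numHeads), mlpRatio = as.numeric(mlpRatio),
      depth = as.integer(depth), patchSize = as.integer(patchSize))
}

#' U-Net model specification
#'
#' @param depth resolution levels (default 5).
#' @param baseChannels channels at level 1 (doubling per level).
#' @param numClasses output classes including background.
#' @param skipModules character vector, one of \code{plain}, \code{skconv},
#'   \code{teb} per level; when NULL the layout is taken from
#'   \code{variant}.
#' @param skSpec,tebSpec module specifications.
#' @param variant one of the named variants (\code{"base"}, \code{"sk"},
#'   \code{"teb"}, \code{"improved"}); used when \code{skipModules} is
#'   NULL.
#' @return A \linkS4class{ModelSpec}.
#' @export
#' @examples
#' modelSpec(variant = "improved")
modelSpec <- function(depth = 5L, baseChannels = 8L, numClasses = 4L,
                      skipModules = NULL, skSpec = skConvSpec(),
                      tebSpec = apexseg::tebSpec(),
                      variant = c("base", "sk", "teb", "improved")) {
  depth <- as.integer(depth)
  if (is.null(skipModules)) {
    variant <- match.arg(variant)
    skipModules <- variantSkipLayout(variant, depth)
  }
  new("ModelSpec", depth = depth, baseChannels = as.integer(baseChannels),
      numClasses = as.integer(numClasses), skipModules = skipModules,
      skSpec = skSpec, tebSpec = tebSpec)
}

#' Skip-module layout of the four named variants
#'
#' \code{base}: all plain; \code{sk}: selective-kernel modules on the first
#' three levels; \code{teb}: transformer blocks on the last two levels;
#' \code{improved}: both.
#'
#' @param variant one of \code{"base"}, \code{"sk"}, \code{"teb"},
#'   \code{"improved"}.
#' @param depth number of levels (the named variants assume 5).
#' @return Character vector of per-level module names.
#' @export
variantSkipLayout <- function(variant = c("base", "sk", "teb", "improved"),
                              depth = 5L) {
  variant <- match.arg(variant)
  lay <- rep("plain", depth)
  if (variant %in% c("sk", "improved")) lay[seq_len(min(3L, depth))] <- "skconv"
  if (variant %in% c("teb", "improved") && depth >= 2L)
    lay[(depth - 1L):depth] <- "teb"
  lay
}

#' The four named model variants
#'
#' @param spec a \linkS4class{ModelSpec} providing depth, channels and module
#'   specs; its own skip layout is ignored.
#' @return Named list of four \linkS4class{ModelSpec} objects:
#'   \code{base}, \code{sk}, \code{teb}, \code{improved}.
#' @export
modelVariants <- function(spec = modelSpec()) {
  lapply(stats::setNames(nm = c("base", "sk", "teb", "improved")), function(v) {
    s <- spec
    s@skipModules <- variantSkipLayout(v, spec@depth)
    s
  })
}

#' Training configuration
#'
#' @param epochs,batchSize counts.
#' @param learningRate Adam step size.
#' @param lossName \code{"cross_entropy"} (default), \code{"dice"} or
#'   \code{"combined"}.
#' @param augmentationOps augmentation op names applied per slice per epoch.
#' @param seed integer.
#' @param checkpointEvery write a checkpoint every this many epochs (0: never).
#' @param checkpointDir directory for checkpoints.
#' @param stopMiou stop early once validation mIoU reaches this value
#'   (NA: run all epochs).
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(epochs = 10L, batchSize = 8L, learningRate = 1e-3,
                        lossName = "cross_entropy", augmentationOps = character(),
                        seed = 1L, checkpointEvery = 0L,
                        checkpointDir = tempfile("ckpt"), stopMiou = NA_real_) {
  new("TrainConfig", epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), lossName = lossName,
      augmentationOps = as.character(augmentationOps), seed = as.integer(seed),
      checkpointEvery = as.integer(checkpointEvery),
      checkpointDir = checkpointDir, stopMiou = as.numeric(stopMiou))
}

#' @rdname phantomAccessors
#' @name phantomAccessors
#' @title Accessors for PhantomSlice and SegReport
#' @param x a \linkS4class{PhantomSlice} or \linkS4class{SegReport}.
#' @return \code{phantomImage}: numeric matrix; \code{phantomMask}: integer
#'   matrix; \code{phantomBoxes}: data.frame; \code{segPerClass}: matrix;
#'   \code{segMeans}: named numeric.
NULL

#' @rdname phantomAccessors
#' @export
phantomImage <- function(x) x@image

#' @rdname phantomAccessors
#' @export
phantomMask <- function(x) x@mask

#' @rdname phantomAccessors
#' @export
phantomBoxes <- function(x) x@boxes

#' @rdname phantomAccessors
#' @export
segPerClass <- function(x) x@perClass

#' @rdname phantomAccessors
#' @export
segMeans <- function(x) c(mIoU = x@mIoU, mDice = x@mDice)
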