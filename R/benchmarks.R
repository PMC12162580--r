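# Desk-scale phantom benchmarks.  One definition shared by the vignette,
# the test suite and scripts/acceptance.R, so every report runs the same
# conditions.
#
# Both benchmarks train with the combined (cross-entropy + soft Dice) loss:
# the optic-canal ring is a thin, heavily class-imbalanced target and the
# Dice term is what makes desk-scale budgets sufficient for it.

#' Easy-phantom learning benchmark
#'
#' Trains the improved variant on the intensity-separable phantom family
#' (200 slices, 64 x 64, 8:2 split) for up to 30 epochs per seed, stopping
#' once validation mIoU over the three foreground structures reaches the
#' target.  The headline question is whether mIoU >= target is reached
#' within the epoch budget in most seeds.
#'
#' @param seeds integer vector of training seeds (default 3 seeds).
#' @param datasetSeed seed of the generated dataset.
#' @param n slices; \code{imageSize} pixels per side.
#' @param imageSize image side in pixels.
#' @param epochs epoch budget per seed.
#' @param target validation mIoU target.
#' @param spec the \linkS4class{ModelSpec} to train (improved by default).
#' @return list: \code{bestMiou} per seed, \code{reached} logical per seed,
#'   \code{epochs} used per seed, \code{logs}.
#' @export
easyBenchmark <- function(seeds = 1:3, datasetSeed = 42L, n = 200L,
                          imageSize = 64L, epochs = 30L, target = 0.90,
                          spec = modelSpec(variant = "improved")) {
  ds <- generateDataset(n, easyPhantomConfig(imageSize = imageSize),
                        seed = datasetSeed)
  out <- list(bestMiou = numeric(0), reached = logical(0),
              epochs = integer(0), logs = list())
  for (sv in seeds) {
    fit <- trainModel(spec, ds$train,
                      trainConfig(epochs = epochs, batchSize = 8L,
                                  learningRate = 3e-3, lossName = "combined",
                                  seed = sv, stopMiou = target),
                      valSet = ds$test)
    best <- max(fit$log$valMiou)
    out$bestMiou <- c(out$bestMiou, best)
    out$reached <- c(out$reached, best >= target)
    out$epochs <- c(out$epochs, fit$epochsRun)
    out$logs[[as.character(sv)]] <- fit$log
  }
  out
}

#' Texture-confusable SK-vs-base benchmark
#'
#' Trains the base and +SK variants under shared seeds on the phantom
#' family whose classes share one mean intensity and differ only in
#' texture period, and reports held-out validation mIoU per seed.  The
#' headline quantity is the mean mIoU gain of +SK over base.
#'
#' @param seeds integer vector of training seeds.
#' @param datasetSeed seed of the generated dataset.
#' @param n slices.
#' @param imageSize image side in pixels.
#' @param epochs fixed epoch budget (no early stop; both variants get the
#'   same budget).
#' @return list: \code{miou} matrix variant x seed, \code{gain} (mean
#'   difference sk - base).
#' @export
textureBenchmark <- function(seeds = 1:3, datasetSeed = 77L, n = 80L,
                             imageSize = 48L, epochs = 20L) {
  ds <- generateDataset(n, textureConfusablePhantomConfig(imageSize = imageSize),
                        seed = datasetSeed)
  miou <- matrix(NA_real_, 2, length(seeds),
                 dimnames = list(c("base", "sk"), seeds))
  for (v in rownames(miou)) {
    for (i in seq_along(seeds)) {
      fit <- trainModel(modelSpec(variant = v), ds$train,
                        trainConfig(epochs = epochs, batchSize = 8L,
                                    learningRate = 3e-3,
                                    lossName = "combined", seed = seeds[i]),
                        valSet = ds$test)
      miou[v, i] <- fit$log$valMiou[nrow(fit$log)]
    }
  }
  list(miou = miou, gain = mean(miou["sk", ]) - mean(miou["base", ]))
}
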