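# Ablation harness: train the four variants (base, +SK, +TEB, improved)
# under shared seeds on one dataset and report held-out per-class IoU/Dice
# plus mIoU/mDice in both background modes, averaged over seeds.

.VARIANTS <- c("base", "sk", "teb", "improved")
.STRUCTS <- c(OC = 1L, ICA = 2L, SS = 3L)

#' Run the four-variant ablation experiment
#'
#' For every seed, the four variants are built from that one seed (so all
#' layers present in every variant start bit-identical) and trained with
#' the same configuration; each trained model is evaluated on the held-out
#' split.  Cells are means over seeds.
#'
#' @param dataset list with \code{train}/\code{test} (e.g. from
#'   \code{\link{generateDataset}}).
#' @param modelBase \linkS4class{ModelSpec} giving depth/channels/module
#'   specs; the variant layouts are derived from it.
#' @param config a \linkS4class{TrainConfig}; its seed slot is replaced by
#'   each element of \code{seeds}.
#' @param seeds integer vector (>= 1 seed).
#' @param variants subset of variants to run (default all four).
#' @return An \linkS4class{AblationResult}.
#' @export
runAblation <- function(dataset, modelBase = modelSpec(), config = trainConfig(),
                        seeds = 1:3, variants = .VARIANTS) {
  stopifnot(length(seeds) >= 1L)
  variants <- match.arg(variants, .VARIANTS, several.ok = TRUE)
  specs <- modelVariants(modelBase)[variants]
  cells <- array(0, c(length(variants), length(.STRUCTS), 2),
                 dimnames = list(variants, names(.STRUCTS), c("IoU", "Dice")))
  means <- matrix(0, length(variants), 4,
                  dimnames = list(variants, c("mIoU", "IoU_bg", "mDice", "Dice_bg")))
  for (v in seq_along(variants)) {
    for (sd in seeds) {
      cfg <- config
      cfg@seed <- as.integer(sd)
      fit <- tryCatch(
        trainModel(specs[[v]], dataset$train, cfg, valSet = dataset$test),
        error = function(e) stop("training failed for variant '", variants[v],
                                 "': ", conditionMessage(e)))
      preds <- lapply(dataset$test, function(s) predictMask(fit$model, s@image))
      truths <- lapply(dataset$test, function(s) s@mask)
      repFg <- evaluateSegmentation(preds, truths,
                                    numClasses = specs[[v]]@numClasses)
      repBg <- meanMetrics(repFg@perClass, includeBackground = TRUE)
      cells[v, , ] <- cells[v, , ] +
        as.matrix(repFg@perClass[as.character(.STRUCTS), , drop = FALSE])
      means[v, ] <- means[v, ] + c(repFg@mIoU, repBg@mIoU, repFg@mDice, repBg@mDice)
    }
  }
  new("AblationResult", cells = cells / length(seeds),
      means = means / length(seeds), seeds = as.integer(seeds),
      configHash = .hashConfig(list(modelBase, config, length(dataset$train))))
}

#' Tabulate an ablation result
#'
#' One row per variant; column order mIoU, IoU-OC, IoU-ICA, IoU-SS, mDice,
#' Dice-OC, Dice-ICA, Dice-SS (foreground means).
#'
#' @param result an \linkS4class{AblationResult}.
#' @param path optional CSV path; when given the table is also written.
#' @return data.frame (invisibly returns it after printing an aligned text
#'   table when \code{print = TRUE}).
#' @param print print an aligned text table.
#' @export
tabulateAblation <- function(result, path = NULL, print = FALSE) {
  df <- data.frame(variant = rownames(result@means),
                   mIoU = result@means[, "mIoU"],
                   `IoU-OC` = result@cells[, "OC", "IoU"],
                   `IoU-ICA` = result@cells[, "ICA", "IoU"],
                   `IoU-SS` = result@cells[, "SS", "IoU"],
                   mDice = result@means[, "mDice"],
                   `Dice-OC` = result@cells[, "OC", "Dice"],
                   `Dice-ICA` = result@cells[, "ICA", "Dice"],
                   `Dice-SS` = result@cells[, "SS", "Dice"],
                   check.names = FALSE, row.names = NULL)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  if (print) {
    fmt <- cbind(variant = format(df$variant, width = 9),
                 format(round(df[-1], 4), nsmall = 4))
    writeLines(capture.output(print(fmt, row.names = FALSE)))
  }
  invisible(df)
}

#' Read back a tabulated ablation CSV
#' @param path CSV path written by \code{\link{tabulateAblation}}.
#' @return data.frame with the same columns.
#' @export
readAblationCsv <- function(path) read.csv(path, check.names = FALSE)
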