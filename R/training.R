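#' Training configuration
#'
#' Defaults give the reference schedule: 480 x 480 inputs, batch size 4,
#' initial learning rate 0.01, SGD with momentum 0.9, 60 epochs, poly
#' learning-rate decay.  Every field is overridable for desk-scale runs;
#' [deskTrainConfig()] is the compact schedule used with small synthetic
#' scenes.
#'
#' @slot inputSize integer, square input resolution.
#' @slot batchSize integer.
#' @slot lr0 numeric, initial learning rate.
#' @slot momentum numeric, SGD momentum.
#' @slot epochs integer.
#' @slot polyPower numeric, exponent of the poly schedule.
#' @slot seed integer, seed for data order and augmentation.
#' @slot loss character, loss identifier (per-pixel cross-entropy).
#' @slot augment logical, random horizontal flip.
#' @export
setClass("TrainConfig", representation(
  inputSize = "integer", batchSize = "integer", lr0 = "numeric",
  momentum = "numeric", epochs = "integer", polyPower = "numeric",
  seed = "integer", loss = "character", augment = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
    if (object@lr0 <= 0) msg <- c(msg, "lr0 must be positive")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be positive")
    if (object@polyPower <= 0) msg <- c(msg, "polyPower must be positive")
    if (!identical(object@loss, "cross-entropy"))
      msg <- c(msg, "only cross-entropy loss is implemented")
    if (length(msg)) msg else TRUE
  })

#' @param inputSize,batchSize,lr0,momentum,epochs,polyPower,seed,loss,augment
#'   see slots.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(inputSize = 480L, batchSize = 4L, lr0 = 0.01,
                        momentum = 0.9, epochs = 60L, polyPower = 0.9,
                        seed = 1L, loss = "cross-entropy", augment = TRUE) {
  new("TrainConfig", inputSize = as.integer(inputSize),
      batchSize = as.integer(batchSize), lr0 = lr0, momentum = momentum,
      epochs = as.integer(epochs), polyPower = polyPower,
      seed = as.integer(seed), loss = loss, augment = isTRUE(augment))
}

#' @param ... overrides passed to [trainConfig()].
#' @rdname TrainConfig-class
#' @export
deskTrainConfig <- function(...) {
  args <- list(inputSize = 96L, epochs = 12L)
  over <- list(...)
  args[names(over)] <- over
  do.call(trainConfig, args)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d x %d, batch %d, lr0 %.4g, momentum %.2f, %d epochs, poly power %.2f, seed %d%s\n",
    object@inputSize, object@inputSize, object@batchSize, object@lr0,
    object@momentum, object@epochs, object@polyPower, object@seed,
    if (object@augment) ", flip augmentation" else ""))
})

#' Poly learning-rate schedule
#'
#' `lr0 * (1 - iteration / maxIterations) ^ power`: non-increasing from
#' `lr0` at iteration 0 to exactly 0 at `maxIterations`.
#'
#' @param iteration current iteration, `0 <= iteration <= maxIterations`.
#' @param maxIterations total iterations (> 0).
#' @param lr0 initial learning rate.
#' @param power schedule exponent.
#' @return the learning rate.
#' @export
polyLR <- function(iteration, maxIterations, lr0 = 0.01, power = 0.9) {
  if (maxIterations <= 0) stop("maxIterations must be positive")
  if (any(iteration < 0) || any(iteration > maxIterations))
    stop("iteration must lie in [0, maxIterations]")
  lr0 * (1 - iteration / maxIterations)^power
}

flipScene <- function(img, msk) {
  W <- dim(img)[2]
  list(img = img[, W:1, , drop = FALSE], msk = msk[, W:1, drop = FALSE])
}

#' Train a segmentation model
#'
#' SGD with momentum on per-pixel cross-entropy, the learning rate following
#' the poly schedule per iteration (`maxIterations = epochs x batches per
#' epoch`).  Data order, augmentation and everything else downstream of the
#' configuration seed are deterministic: two runs with the same seed produce
#' identical loss traces.  Scenes must share one size, divisible by 16.
#'
#' @param model a [SegModel-class]; updated in place.
#' @param scenes non-empty list of [LabeledScene-class] training scenes.
#' @param config a [TrainConfig-class].
#' @param verbose print a line per epoch.
#' @param checkpointPath optional path; a checkpoint is written there after
#'   every epoch.
#' @return list with `model` and `trace`, a data.frame with one row per
#'   iteration (iteration, epoch, lr, loss).
#' @export
trainModel <- function(model, scenes, config = deskTrainConfig(),
                       verbose = FALSE, checkpointPath = NULL) {
  validObject(config)
  if (!length(scenes)) stop("training set is empty")
  nc <- model@variant@numClasses
  for (s in scenes)
    if (max(s@mask) >= nc)
      stop(sprintf("scene '%s' has labels >= numClasses (%d)", s@sceneId, nc))
  N <- length(scenes)
  bs <- config@batchSize
  batchesPerEpoch <- ceiling(N / bs)
  maxIter <- config@epochs * batchesPerEpoch
  trace <- vector("list", maxIter)
  iter <- 0L
  withSeed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(N)
      for (b in seq_len(batchesPerEpoch)) {
        ids <- ord[((b - 1L) * bs + 1L):min(b * bs, N)]
        d <- dim(scenes[[ids[1]]]@image)
        x <- array(0, c(d[1], d[2], 3L, length(ids)))
        tg <- array(0L, c(d[1], d[2], length(ids)))
        for (i in seq_along(ids)) {
          sc <- scenes[[ids[i]]]
          img <- sc@image; msk <- sc@mask
          if (config@augment && stats::runif(1) < 0.5) {
            fl <- flipScene(img, msk)
            img <- fl$img; msk <- fl$msk
          }
          x[, , , i] <- img
          tg[, , i] <- msk
        }
        storage.mode(tg) <- "integer"
        lr <- polyLR(iter, maxIter, config@lr0, config@polyPower)
        logits <- segForward(model, x, training = TRUE)
        ce <- cs_softmax_ce(logits, tg)
        if (!is.finite(ce$loss))
          stop(sprintf(
            "non-finite loss at iteration %d (epoch %d, lr %.3g, batch scenes: %s)",
            iter, epoch, lr,
            paste(vapply(scenes[ids], function(s) s@sceneId, ""), collapse = ", ")))
        segBackward(model, ce$dx)
        sgdStep(model@net$params, lr, config@momentum)
        zeroGrads(model@net$params)
        iter <- iter + 1L
        trace[[iter]] <- c(iteration = iter, epoch = epoch, lr = lr,
                           loss = ce$loss)
      }
      if (verbose) {
        recent <- do.call(rbind, trace[(iter - batchesPerEpoch + 1L):iter])
        message(sprintf("epoch %3d/%d  mean loss %.4f  lr %.5f",
                        epoch, config@epochs, mean(recent[, "loss"]),
                        recent[1, "lr"]))
      }
      if (!is.null(checkpointPath)) saveCheckpoint(model, checkpointPath)
    }
  })
  list(model = model,
       trace = as.data.frame(do.call(rbind, trace)))
}

#' Evaluate a model on a scene set
#'
#' Accumulates a single confusion matrix over all scenes at native
#' resolution (inference mode, no resizing — the metrics are pixel counts)
#' and returns the metrics report.
#'
#' @param model a [SegModel-class], or a function `image -> mask` (an oracle
#'   stub, useful for testing the harness).
#' @param scenes non-empty list of [LabeledScene-class].
#' @param classNames labels for the confusion matrix.
#' @param cpaMode per-class accuracy mode, see [metricsReport()].
#' @return a [MetricsReport-class] (the confusion matrix is in slot `cm`).
#' @export
evaluateModel <- function(model, scenes,
                          classNames = c("background", "cow", "beef"),
                          cpaMode = "precision") {
  if (!length(scenes)) stop("evaluation set is empty")
  cm <- confusionMatrix(classNames)
  for (sc in scenes) {
    pred <- if (is.function(model)) model(sc@image) else predictMask(model, sc@image)
    cm <- cmAccumulate(cm, pred, sc@mask)
  }
  metricsReport(cm, cpaMode = cpaMode)
}

#' Train and evaluate a grid of model variants
#'
#' Trains each variant under identical seeds and data and evaluates it on
#' each test set, producing the conventional ablation table (one row per
#' variant and test set, columns PA, MPA, MIoU and the per-class CPA/IoU).
#' A failure in one variant is recorded in its rows and the remaining
#' variants still run.
#'
#' @param variants named list of [ModelVariant-class]; names label the rows.
#' @param trainScenes list of training scenes.
#' @param testSets a list of test scenes, or a named list of several such
#'   lists (e.g. `list(mixed = ..., sunny = ..., foggy = ...)`).
#' @param config a [TrainConfig-class]; the same seed is used for every
#'   variant.
#' @param options [networkOptions()] for model construction.
#' @param percent report percentages.
#' @param verbose print progress.
#' @return data.frame: Model, TestSet, then the seven metric columns.
#' @export
runAblation <- function(variants, trainScenes, testSets,
                        config = deskTrainConfig(),
                        options = deskNetworkOptions(), percent = FALSE,
                        verbose = FALSE) {
  if (!length(variants)) stop("need at least one variant")
  if (is.null(names(variants)))
    names(variants) <- vapply(variants, variantName, "")
  if (is(testSets[[1]], "LabeledScene")) testSets <- list(test = testSets)
  rows <- list()
  for (vn in names(variants)) {
    row <- tryCatch({
      model <- buildModel(variants[[vn]], options)
      trainModel(model, trainScenes, config, verbose = verbose)
      lapply(names(testSets), function(tn) {
        rep <- evaluateModel(model, testSets[[tn]])
        cbind(data.frame(Model = vn, TestSet = tn), metricsRow(rep, percent))
      })
    }, error = function(e) {
      warning(sprintf("variant '%s' failed: %s", vn, conditionMessage(e)))
      cols <- c("PA", "MPA", "MIoU", "CPA(Cow)", "CPA(Beef)",
                "IoU(Cow)", "IoU(Beef)")
      lapply(names(testSets), function(tn) {
        out <- data.frame(Model = vn, TestSet = tn, check.names = FALSE)
        for (cl in cols) out[[cl]] <- NA_real_
        out
      })
    })
    rows <- c(rows, row)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
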