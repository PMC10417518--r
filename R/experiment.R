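#' Experiment configuration
#'
#' One replayable artifact: scene recipe, model variant, network options,
#' training schedule and fog protocol, serialisable to a single YAML file.
#' Re-running the same file reproduces all deterministic outputs.
#'
#' @slot recipe a [SceneRecipe-class].
#' @slot variant a [ModelVariant-class].
#' @slot train a [TrainConfig-class].
#' @slot options [networkOptions()] list.
#' @slot nScenes integer, number of scenes to generate.
#' @slot splitRatio numeric, training fraction.
#' @slot fogFraction numeric, fraction of the test set fogged in the mixed
#'   protocol.
#' @slot betaRange numeric length-2 fog-strength range.
#' @slot outputDir character.
#' @export
setClass("ExperimentConfig", representation(
  recipe = "SceneRecipe", variant = "ModelVariant", train = "TrainConfig",
  options = "list", nScenes = "integer", splitRatio = "numeric",
  fogFraction = "numeric", betaRange = "numeric", outputDir = "character"))

#' @param recipe,variant,train,options,nScenes,splitRatio,fogFraction,betaRange,outputDir
#'   see slots; defaults give the desk-scale setup (96 x 96, 200 scenes).
#' @rdname ExperimentConfig-class
#' @export
experimentConfig <- function(recipe = sceneRecipe(), variant = impVariant(),
                             train = deskTrainConfig(),
                             options = deskNetworkOptions(),
                             nScenes = 200L, splitRatio = 0.8,
                             fogFraction = 0.5, betaRange = c(0.8, 2.0),
                             outputDir = "cattleseg-run") {
  new("ExperimentConfig", recipe = recipe, variant = variant, train = train,
      options = options, nScenes = as.integer(nScenes),
      splitRatio = splitRatio, fogFraction = fogFraction,
      betaRange = as.numeric(betaRange), outputDir = outputDir)
}

#' Read / write an experiment configuration as YAML
#'
#' @param config an [ExperimentConfig-class].
#' @param path YAML file path.
#' @return `readExperimentConfig` returns an [ExperimentConfig-class].
#' @export
writeExperimentConfig <- function(config, path) {
  r <- config@recipe; v <- config@variant; t <- config@train
  yaml::write_yaml(list(
    recipe = list(canvasSize = r@canvasSize, nAnimals = r@nAnimals,
                  classMix = r@classMix, occluderRate = r@occluderRate,
                  animalScale = r@animalScale, seed = r@seed),
    variant = list(decoderStyle = v@decoderStyle, useSE = v@useSE,
                   numClasses = v@numClasses),
    train = list(inputSize = t@inputSize, batchSize = t@batchSize,
                 lr0 = t@lr0, momentum = t@momentum, epochs = t@epochs,
                 polyPower = t@polyPower, seed = t@seed, loss = t@loss,
                 augment = t@augment),
    options = config@options,
    nScenes = config@nScenes, splitRatio = config@splitRatio,
    fogFraction = config@fogFraction, betaRange = config@betaRange,
    outputDir = config@outputDir), path)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  experimentConfig(
    recipe = do.call(sceneRecipe, y$recipe),
    variant = do.call(modelVariant, y$variant),
    train = do.call(trainConfig, y$train),
    options = do.call(networkOptions, y$options),
    nScenes = y$nScenes, splitRatio = y$splitRatio,
    fogFraction = y$fogFraction, betaRange = unlist(y$betaRange),
    outputDir = y$outputDir)
}

#' Alpha-blended class overlay
#'
#' Blends the palette colour of each non-background class over the image
#' (cow red, beef green), the usual way qualitative segmentation results are
#' displayed.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask integer `H x W` label matrix.
#' @param alpha blend weight of the class colour.
#' @return `H x W x 3` array.
#' @export
overlayMask <- function(image, mask, alpha = 0.45) {
  pal <- classPalette(max(3L, max(mask) + 1L))
  out <- image
  fg <- mask > 0
  for (chn in 1:3) {
    plane <- out[, , chn]
    plane[fg] <- (1 - alpha) * plane[fg] + alpha * pal[mask[fg] + 1L, chn]
    out[, , chn] <- plane
  }
  out
}

#' Run a full experiment
#'
#' Generates the synthetic dataset from the recipe, splits it, applies the
#' fog protocol to the test part, trains the selected variant, evaluates on
#' the mixed / sunny / foggy test sets, and writes every artifact (metrics
#' tables, loss trace, checkpoint, sample prediction overlays, manifest with
#' content hashes, and the resolved configuration) into `outputDir`.
#'
#' @param config an [ExperimentConfig-class].
#' @param verbose print progress.
#' @param nOverlays number of test scenes to render as overlays.
#' @return a bundle list: `ok`, `stage` (last stage reached), `reports`
#'   (named [MetricsReport-class] list), `trace`, `files`, `manifest`.
#' @export
runExperiment <- function(config, verbose = FALSE, nOverlays = 4L) {
  out <- config@outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(ok = FALSE, stage = "init", files = character(0))
  fail <- function(stage, e) {
    bundle$stage <- stage
    bundle$error <- conditionMessage(e)
    bundle
  }

  scenes <- tryCatch({
    bundle$stage <- "data"
    generateScenes(config@recipe, config@nScenes)
  }, error = function(e) NULL)
  if (is.null(scenes)) return(fail("data", simpleError("scene generation failed")))

  tryCatch({
    sp <- splitDataset(scenes, config@splitRatio, seed = config@recipe@seed)
    proto <- fogTestProtocol(sp$test, config@fogFraction, config@betaRange,
                             seed = config@recipe@seed)

    bundle$stage <- "train"
    model <- buildModel(config@variant, config@options)
    fit <- trainModel(model, sp$train, config@train, verbose = verbose)

    bundle$stage <- "evaluate"
    reports <- list(
      mixed = evaluateModel(model, proto$mixed),
      sunny = evaluateModel(model, proto$sunny),
      foggy = evaluateModel(model, proto$foggy))

    bundle$stage <- "write"
    files <- c(
      config = file.path(out, "config.yaml"),
      trace = file.path(out, "loss_trace.csv"),
      checkpoint = file.path(out, "checkpoint.rds"))
    writeExperimentConfig(config, files[["config"]])
    utils::write.csv(fit$trace, files[["trace"]], row.names = FALSE)
    saveCheckpoint(model, files[["checkpoint"]])
    for (nm in names(reports)) {
      f <- file.path(out, sprintf("metrics_%s.csv", nm))
      writeMetrics(stats::setNames(list(reports[[nm]]),
                                   variantName(config@variant)), f,
                   percent = TRUE)
      files[[paste0("metrics_", nm)]] <- f
    }
    for (i in seq_len(min(nOverlays, length(proto$mixed)))) {
      sc <- proto$mixed[[i]]
      ov <- overlayMask(sc@image, predictMask(model, sc@image))
      f <- file.path(out, sprintf("overlay_%s.png", sc@sceneId))
      png::writePNG(ov, f)
      files[[sprintf("overlay%d", i)]] <- f
    }

    manifest <- data.frame(file = basename(unname(files)),
                           md5 = unname(tools::md5sum(unname(files))))
    manifestPath <- file.path(out, "manifest.csv")
    utils::write.csv(manifest, manifestPath, row.names = FALSE)

    bundle$ok <- TRUE
    bundle$stage <- "done"
    bundle$model <- model
    bundle$reports <- reports
    bundle$trace <- fit$trace
    bundle$files <- c(files, manifest = manifestPath)
    bundle$manifest <- manifest
    bundle
  }, error = function(e) fail(bundle$stage, e))
}
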