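#' Model variant selector
#'
#' Selects the decoder style and whether squeeze-and-excitation attention is
#' attached, realising the ablation grid: `layerwise + SE` is the full
#' improved model (Imp), `layerwise` without SE is the M2-U variant, and
#' `simple` without SE is the M2 variant (MobileNetV2 backbone with the
#' original one-fusion decoder).
#'
#' @slot decoderStyle `"layerwise"` or `"simple"`.
#' @slot useSE logical.
#' @slot numClasses integer, number of segmentation classes (default 3:
#'   background, cow, beef).
#' @export
setClass("ModelVariant", representation(
  decoderStyle = "character", useSE = "logical", numClasses = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@decoderStyle %in% c("layerwise", "simple"))
      msg <- c(msg, "decoderStyle must be 'layerwise' or 'simple'")
    if (object@numClasses < 1L) msg <- c(msg, "numClasses must be positive")
    if (length(msg)) msg else TRUE
  })

#' @param decoderStyle,useSE,numClasses see slots.
#' @rdname ModelVariant-class
#' @export
modelVariant <- function(decoderStyle = c("layerwise", "simple"),
                         useSE = FALSE, numClasses = 3L) {
  new("ModelVariant", decoderStyle = match.arg(decoderStyle),
      useSE = isTRUE(useSE), numClasses = as.integer(numClasses))
}

#' @rdname ModelVariant-class
#' @export
impVariant <- function(numClasses = 3L) modelVariant("layerwise", TRUE, numClasses)

#' @rdname ModelVariant-class
#' @export
m2uVariant <- function(numClasses = 3L) modelVariant("layerwise", FALSE, numClasses)

#' @rdname ModelVariant-class
#' @export
m2Variant <- function(numClasses = 3L) modelVariant("simple", FALSE, numClasses)

#' @param variant a [ModelVariant-class].
#' @rdname ModelVariant-class
#' @export
variantName <- function(variant) {
  if (variant@decoderStyle == "layerwise")
    return(if (variant@useSE) "Imp-DeepLabV3+" else "M2-U-DeepLabV3+")
  if (variant@useSE) "M2-SE-DeepLabV3+" else "M2-DeepLabV3+"
}

setMethod("show", "ModelVariant", function(object) {
  cat(sprintf("ModelVariant: %s (decoder = %s, SE = %s, classes = %d)\n",
              variantName(object), object@decoderStyle,
              if (object@useSE) "yes" else "no", object@numClasses))
})

#' Network hyper-parameters
#'
#' Structural settings that do not change the architecture family: channel
#' widths, atrous rates, batch-norm constants and the weight-initialisation
#' seed.  `networkOptions()` gives the reference widths (multiplier 1,
#' 256-channel decoder); `deskNetworkOptions()` gives a compact configuration
#' (width multiplier 0.35 — MobileNet's own slimming knob — and a 48-channel
#' decoder) sized for CPU-scale experiments on small synthetic scenes.
#'
#' @param widthMultiplier MobileNet width multiplier for the backbone.
#' @param decoderChannels refinement width in the decoder.
#' @param reduceChannels width of the 1x1 skip reductions before fusion.
#' @param asppChannels ASPP projection width.
#' @param asppRates atrous rates of the ASPP branches.
#' @param seReduction squeeze-and-excitation bottleneck ratio.
#' @param bnEps,bnMomentum batch normalisation epsilon and running-stat
#'   momentum (new-value weight).
#' @param seed integer seed for weight initialisation.
#' @return named list of options.
#' @export
networkOptions <- function(widthMultiplier = 1, decoderChannels = 256L,
                           reduceChannels = 48L, asppChannels = 256L,
                           asppRates = c(6L, 12L, 18L), seReduction = 16L,
                           bnEps = 1e-5, bnMomentum = 0.1, seed = 1L) {
  list(widthMultiplier = widthMultiplier,
       decoderChannels = as.integer(decoderChannels),
       reduceChannels = as.integer(reduceChannels),
       asppChannels = as.integer(asppChannels),
       asppRates = as.integer(asppRates),
       seReduction = as.integer(seReduction),
       bnEps = bnEps, bnMomentum = bnMomentum, seed = as.integer(seed))
}

#' @rdname networkOptions
#' @export
deskNetworkOptions <- function(seed = 1L) {
  networkOptions(widthMultiplier = 0.35, decoderChannels = 48L,
                 reduceChannels = 16L, asppChannels = 96L, seReduction = 8L,
                 seed = seed)
}

#' Segmentation model
#'
#' Composes backbone, ASPP head and decoder.  The forward pass maps an
#' `H x W x 3 x N` image batch (values in `[0, 1]`) to per-pixel class scores
#' of shape `H x W x numClasses x N`; the predicted mask is the per-pixel
#' argmax.  Weights live in an environment so training updates in place.
#'
#' @slot variant the [ModelVariant-class] realised.
#' @slot options the [networkOptions()] list used at construction.
#' @slot net environment holding the module tree.
#' @export
setClass("SegModel", representation(
  variant = "ModelVariant", options = "list", net = "environment"))

#' Build a segmentation network
#'
#' @param variant a [ModelVariant-class] ([impVariant()], [m2uVariant()],
#'   [m2Variant()]).
#' @param options a [networkOptions()] list.
#' @param backbone optional [BackboneConfig-class]; defaults to the reference
#'   stage table with the options' width multiplier applied.
#' @return a [SegModel-class].
#' @examples
#' m <- buildModel(impVariant(), deskNetworkOptions(seed = 7))
#' x <- array(stats::runif(32 * 32 * 3), c(32, 32, 3, 1))
#' dim(segForward(m, x))      # 32 32 3 1
#' @export
buildModel <- function(variant = impVariant(), options = networkOptions(),
                       backbone = NULL) {
  validObject(variant)
  if (is.null(backbone))
    backbone <- backboneConfig(widthMultiplier = options$widthMultiplier)
  net <- new.env(parent = emptyenv())
  withSeed(options$seed, {
    net$backbone <- buildBackbone(backbone, 3L, options$bnEps, options$bnMomentum)
    net$aspp <- buildASPP(net$backbone$outChannels, options$asppChannels,
                          options$asppRates, options$bnEps, options$bnMomentum)
    net$decoder <- buildDecoder(
      style = variant@decoderStyle, useSE = variant@useSE,
      inChannels = options$asppChannels,
      tapChannels = net$backbone$tapChannels,
      numClasses = variant@numClasses,
      width = options$decoderChannels,
      reduceChannels = options$reduceChannels,
      seReduction = options$seReduction,
      bnEps = options$bnEps, bnMomentum = options$bnMomentum)
  })
  root <- csModule("root")
  root$children <- list(backbone = net$backbone, aspp = net$aspp,
                        decoder = net$decoder)
  net$root <- root
  net$params <- collectParams(root)
  new("SegModel", variant = variant, options = options, net = net)
}

#' Forward pass of a segmentation model
#'
#' @param model a [SegModel-class].
#' @param x image batch, array `H x W x 3 x N` with `H`, `W` divisible by 16.
#' @param training logical; `TRUE` uses batch statistics in batch norm and
#'   caches activations for a subsequent backward pass, `FALSE` runs pure
#'   inference with running statistics.
#' @return class-score array `H x W x numClasses x N`.
#' @export
segForward <- function(model, x, training = FALSE) {
  stopifnot(is(model, "SegModel"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  b <- model@net$backbone$forward(x, training)
  a <- model@net$aspp$forward(b$out, training)
  model@net$decoder$forward(a, b$taps, training)
}

# Backward pass matching the last training-mode forward; accumulates
# parameter gradients and returns the input gradient.
segBackward <- function(model, dlogits) {
  d <- model@net$decoder$backward(dlogits)
  daspp <- model@net$aspp$backward(d$dx)
  model@net$backbone$backward(list(out = daspp, taps = d$taps))
}

#' Predict a segmentation mask
#'
#' Runs inference and takes the per-pixel argmax over class scores.
#'
#' @param model a [SegModel-class].
#' @param x an image array (`H x W x 3` or `H x W x 3 x N`) or a
#'   [LabeledScene-class].
#' @return integer label matrix `H x W` (or `H x W x N` array), 0-based.
#' @export
predictMask <- function(model, x) {
  if (is(x, "LabeledScene")) x <- x@image
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L)
  lab <- cs_channel_argmax(segForward(model, x, training = FALSE))
  if (single) lab <- array(lab, dim(lab)[1:2])
  lab
}

#' Number of trainable parameters
#' @param model a [SegModel-class].
#' @return integer count over all weights, biases and batch-norm affines.
#' @export
paramCount <- function(model) {
  sum(vapply(model@net$params, function(p) length(p$v), numeric(1)))
}

#' Analytic layer shapes for a model input size
#'
#' Traces spatial dimensions through backbone, head and decoder without
#' computing anything, so construction contracts (output stride 16, decoder
#' up-sampling structure, full-resolution logits) can be checked in
#' milliseconds even at the 480 x 480 reference size.
#'
#' @param model a [SegModel-class].
#' @param inputSize integer length-2 (H, W), divisible by 16.
#' @return list: `backbone` data.frame, `deepest` c(H, W, C), `taps`,
#'   `logits` c(H, W, numClasses).
#' @export
modelShapes <- function(model, inputSize = c(480L, 480L)) {
  if (any(inputSize %% 16L != 0L)) {
    ax <- c("height", "width")[which(inputSize %% 16L != 0L)[1]]
    stop(sprintf("input %s %d is not divisible by 16", ax,
                 inputSize[which(inputSize %% 16L != 0L)[1]]))
  }
  cfg <- model@net$backbone$config
  sh <- backboneShapes(inputSize, cfg@stages, cfg@stemChannels,
                       cfg@widthMultiplier)
  last <- sh[nrow(sh), ]
  taps <- list(
    `2` = c(inputSize %/% 2L, unname(model@net$backbone$tapChannels["2"])),
    `4` = c(inputSize %/% 4L, unname(model@net$backbone$tapChannels["4"])),
    `8` = c(inputSize %/% 8L, unname(model@net$backbone$tapChannels["8"])))
  list(backbone = sh,
       deepest = c(last$H, last$W, last$channels),
       taps = taps,
       logits = c(inputSize, model@variant@numClasses))
}

setMethod("show", "SegModel", function(object) {
  cat(sprintf("SegModel: %s\n", variantName(object@variant)))
  cat(sprintf("  backbone width multiplier: %g (deepest map %d channels)\n",
              object@options$widthMultiplier, object@net$backbone$outChannels))
  cat(sprintf("  ASPP: %d branches (rates %s) -> %d channels\n",
              object@net$aspp$nBranches,
              paste(object@net$aspp$rates, collapse = ", "),
              object@net$aspp$outChannels))
  cat(sprintf("  decoder: %s, %d upsamplings (x%s), %d fusion(s), SE %s\n",
              object@net$decoder$style, object@net$decoder$nUpsample,
              paste(object@net$decoder$upFactors, collapse = " x"),
              object@net$decoder$nFusions,
              if (object@variant@useSE) "on" else "off"))
  cat(sprintf("  parameters: %s\n", format(paramCount(object), big.mark = ",")))
})

#' Pin squeeze-and-excitation weights to 1
#'
#' Forces every excitation weight to exactly 1 so each SE block becomes an
#' identity; with pinned excitation the full model's forward pass must equal
#' the SE-free layerwise variant given shared weights.
#'
#' @param model a [SegModel-class].
#' @param pinned logical.
#' @return the model, invisibly (modified in place).
#' @export
pinExcitation <- function(model, pinned = TRUE) {
  walk <- function(mod) {
    if (identical(mod$type, "se")) mod$pinned <- pinned
    for (ch in mod$children) walk(ch)
  }
  walk(model@net$root)
  invisible(model)
}

#' Copy weights between structurally aligned models
#'
#' Copies every parameter and batch-norm running statistic whose module path
#' exists in both models (for example from an SE-equipped model to its
#' SE-free counterpart, which share all non-SE weights).
#'
#' @param from,to [SegModel-class] objects.
#' @return `to`, invisibly (modified in place); the number of copied
#'   parameters is attached as attribute `"copied"`.
#' @export
copyMatchingParams <- function(from, to) {
  pf <- from@net$params
  pt <- to@net$params
  shared <- intersect(names(pf), names(pt))
  for (nm in shared) {
    if (!identical(dim(pf[[nm]]$v), dim(pt[[nm]]$v)) &&
        length(pf[[nm]]$v) != length(pt[[nm]]$v))
      stop(sprintf("parameter %s has incompatible shapes", nm))
    pt[[nm]]$v <- pf[[nm]]$v
  }
  restoreBNStats(to@net$root, collectBNStats(from@net$root))
  res <- invisible(to)
  attr(res, "copied") <- length(shared)
  invisible(res)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the variant and every construction option, so
#' loading reconstructs the exact architecture before restoring weights and
#' batch-norm running statistics.
#'
#' @param model a [SegModel-class].
#' @param path file path.
#' @return `loadCheckpoint` returns a [SegModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  v <- model@variant
  saveRDS(list(
    format = "cattleseg-checkpoint-1",
    variant = list(decoderStyle = v@decoderStyle, useSE = v@useSE,
                   numClasses = v@numClasses),
    options = model@options,
    params = lapply(model@net$params, function(p) p$v),
    bnStats = collectBNStats(model@net$root)), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "cattleseg-checkpoint-1"))
    stop("not a cattleseg checkpoint: ", path)
  variant <- modelVariant(ck$variant$decoderStyle, ck$variant$useSE,
                          ck$variant$numClasses)
  model <- buildModel(variant, ck$options)
  for (nm in names(ck$params)) {
    p <- model@net$params[[nm]]
    if (is.null(p)) stop("checkpoint parameter not in model: ", nm)
    p$v <- ck$params[[nm]]
  }
  restoreBNStats(model@net$root, ck$bnStats)
  model
}
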