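#' @import methods
NULL

#' One backbone stage specification
#'
#' A stage is a run of inverted-residual bottleneck blocks sharing an
#' expansion factor, output width, stride (applied by the first block only)
#' and atrous dilation rate.  Stride 2 and dilation > 1 are never combined
#' within a stage: a stage either halves resolution or enlarges its receptive
#' field, not both.
#'
#' @slot expansion integer, bottleneck expansion factor t.
#' @slot outChannels integer, output channels c.
#' @slot repeats integer, number of block repetitions n.
#' @slot stride integer in {1, 2}, stride s of the first block.
#' @slot dilation integer >= 1, atrous rate of the depthwise convolutions.
#' @export
setClass("StageSpec", representation(
  expansion = "integer", outChannels = "integer", repeats = "integer",
  stride = "integer", dilation = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@expansion < 1L) msg <- c(msg, "expansion must be positive")
    if (object@outChannels < 1L) msg <- c(msg, "outChannels must be positive")
    if (object@repeats < 1L) msg <- c(msg, "repeats must be positive")
    if (!object@stride %in% c(1L, 2L)) msg <- c(msg, "stride must be 1 or 2")
    if (object@dilation < 1L) msg <- c(msg, "dilation must be positive")
    if (object@stride == 2L && object@dilation != 1L)
      msg <- c(msg, "stride 2 and dilation > 1 must not be combined in a stage")
    if (length(msg)) msg else TRUE
  })

#' @param expansion,outChannels,repeats,stride,dilation see slots.
#' @rdname StageSpec-class
#' @export
stageSpec <- function(expansion, outChannels, repeats, stride, dilation = 1L) {
  new("StageSpec", expansion = as.integer(expansion),
      outChannels = as.integer(outChannels), repeats = as.integer(repeats),
      stride = as.integer(stride), dilation = as.integer(dilation))
}

#' Backbone configuration
#'
#' The truncated MobileNetV2 feature extractor: a stride-2 stem convolution
#' followed by seven bottleneck stages.  The default configuration keeps the
#' nominal strides down to 1/16 resolution and then switches the deepest
#' stage to stride 1 with atrous rate 2, so the cumulative stride (output
#' stride) is 16 rather than 32.  Intermediate maps at down-sampling factors
#' 2, 4 and 8 are exposed to the decoder.
#'
#' @slot stemChannels integer, stem convolution width (stride fixed at 2).
#' @slot stages list of [StageSpec-class] rows.
#' @slot widthMultiplier numeric, MobileNet width multiplier applied to every
#'   channel count (rounded to a multiple of 8); 1 reproduces the reference
#'   widths.
#' @export
setClass("BackboneConfig", representation(
  stemChannels = "integer", stages = "list", widthMultiplier = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!all(vapply(object@stages, is, TRUE, "StageSpec")))
      msg <- c(msg, "stages must all be StageSpec")
    st <- 2L
    for (s in object@stages) st <- st * s@stride
    if (st != 16L)
      msg <- c(msg, sprintf("cumulative stride must be 16, got %d", st))
    if (object@widthMultiplier <= 0) msg <- c(msg, "widthMultiplier must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @param widthMultiplier numeric width multiplier.
#' @param stages optional list of [StageSpec-class]; default is the
#'   eight-row reference configuration (stem row plus seven bottleneck
#'   stages) with the deepest stage at stride 1, dilation 2.
#' @param stemChannels stem width before the multiplier.
#' @rdname BackboneConfig-class
#' @export
backboneConfig <- function(widthMultiplier = 1, stages = NULL,
                           stemChannels = 32L) {
  if (is.null(stages)) stages <- defaultBackboneStages()
  new("BackboneConfig", stemChannels = as.integer(stemChannels),
      stages = stages, widthMultiplier = as.numeric(widthMultiplier))
}

#' @rdname BackboneConfig-class
#' @export
defaultBackboneStages <- function() {
  list(
    stageSpec(1, 16, 1, 1, 1),
    stageSpec(6, 24, 2, 2, 1),
    stageSpec(6, 32, 3, 2, 1),
    stageSpec(6, 64, 4, 2, 1),
    stageSpec(6, 96, 3, 1, 1),
    stageSpec(6, 160, 3, 1, 1),
    stageSpec(6, 320, 1, 1, 2))
}

# Nominal MobileNetV2 strides (output stride 32); used by the output-stride
# property test, not by any built network (cumulative stride 32 fails the
# BackboneConfig validity on purpose, so shape inference works on the raw
# stage list instead).
nominalBackboneStages <- function() {
  st <- defaultBackboneStages()
  st[[6]] <- stageSpec(6, 160, 3, 2, 1)
  st[[7]] <- stageSpec(6, 320, 1, 1, 1)
  st
}

scaledChannels <- function(config) {
  a <- config@widthMultiplier
  scale1 <- function(c) if (a == 1) as.integer(c) else makeDivisible(c * a)
  list(stem = scale1(config@stemChannels),
       stages = vapply(config@stages, function(s) scale1(s@outChannels), 1L))
}

# ---- inverted residual block ------------------------------------------------

# 1x1 expansion -> 3x3 depthwise (stride, dilation) -> 1x1 linear projection,
# with an identity shortcut when stride is 1 and widths match.
invertedResidual <- function(inC, outC, stride, expansion, dilation = 1L,
                             bnEps = 1e-5, bnMomentum = 0.1) {
  m <- csModule("invres")
  hidden <- as.integer(inC * expansion)
  mods <- list()
  if (expansion != 1L)
    mods$expand <- cbaLayer(inC, hidden, 1L, act = "relu6",
                            bnEps = bnEps, bnMomentum = bnMomentum)
  mods$dw <- seqLayer(list(
    dwconvLayer(hidden, 3L, stride, dilation),
    bnLayer(hidden, bnEps, bnMomentum),
    actLayer("relu6")))
  mods$project <- seqLayer(list(
    convLayer(hidden, outC, 1L),
    bnLayer(outC, bnEps, bnMomentum)))
  m$children <- mods
  m$residual <- (stride == 1L && inC == outC)
  m$forward <- function(x, training = TRUE) {
    y <- x
    for (ch in m$children) y <- ch$forward(y, training)
    if (m$residual) y <- y + x
    y
  }
  m$backward <- function(dy) {
    g <- dy
    for (ch in rev(m$children)) g <- ch$backward(g)
    if (m$residual) g <- g + dy
    g
  }
  m
}

# ---- backbone ---------------------------------------------------------------

#' Build the truncated MobileNetV2 feature extractor
#'
#' Returns a module whose forward pass maps an `H x W x 3 x N` batch to a
#' list with the deepest feature map (`H/16 x W/16`) under `$out` and the
#' skip maps at down-sampling factors 2, 4 and 8 under `$taps`.  Input height
#' and width must be divisible by 16.
#'
#' @param config a [BackboneConfig-class].
#' @param inChannels number of image channels (3 for RGB).
#' @param bnEps,bnMomentum batch-norm settings.
#' @return a backbone module; see also [backboneChannels()] and
#'   [backboneShapes()].
#' @export
buildBackbone <- function(config = backboneConfig(), inChannels = 3L,
                          bnEps = 1e-5, bnMomentum = 0.1) {
  validObject(config)
  ch <- scaledChannels(config)
  m <- csModule("backbone")
  m$config <- config

  makeStage <- function(inC, spec, outC) {
    blocks <- list()
    for (i in seq_len(spec@repeats)) {
      blocks[[i]] <- invertedResidual(
        if (i == 1L) inC else outC, outC,
        stride = if (i == 1L) spec@stride else 1L,
        expansion = spec@expansion, dilation = spec@dilation,
        bnEps = bnEps, bnMomentum = bnMomentum)
    }
    seqLayer(blocks)
  }

  stem <- cbaLayer(inChannels, ch$stem, 3L, stride = 2L, act = "relu6",
                   bnEps = bnEps, bnMomentum = bnMomentum,
                   needInputGrad = TRUE)
  stages <- list()
  inC <- ch$stem
  for (i in seq_along(config@stages)) {
    stages[[i]] <- makeStage(inC, config@stages[[i]], ch$stages[i])
    inC <- ch$stages[i]
  }

  # Segment boundaries: the tap at each resolution is the last map produced
  # at that resolution before the next stride-2 operation.
  # seg1 = stem + stage1 (1/2), seg2 = stage2 (1/4), seg3 = stage3 (1/8),
  # seg4 = stages 4..7 (1/16, the deepest map).
  m$children <- list(
    seg1 = seqLayer(c(list(stem), stages[1])),
    seg2 = stages[[2]],
    seg3 = stages[[3]],
    seg4 = seqLayer(stages[4:7]))
  m$tapChannels <- c(`2` = ch$stages[1], `4` = ch$stages[2], `8` = ch$stages[3])
  m$outChannels <- ch$stages[length(ch$stages)]

  m$forward <- function(x, training = TRUE) {
    d <- dim(x)
    if (d[1] %% 16L != 0L)
      stop(sprintf("input height %d is not divisible by 16", d[1]))
    if (d[2] %% 16L != 0L)
      stop(sprintf("input width %d is not divisible by 16", d[2]))
    t2 <- m$children$seg1$forward(x, training)
    t4 <- m$children$seg2$forward(t2, training)
    t8 <- m$children$seg3$forward(t4, training)
    out <- m$children$seg4$forward(t8, training)
    list(out = out, taps = list(`2` = t2, `4` = t4, `8` = t8))
  }
  # grads: list(out =, taps = list(`2`,`4`,`8`)); missing entries are zero.
  m$backward <- function(grads) {
    g <- m$children$seg4$backward(grads$out)
    if (!is.null(grads$taps[["8"]])) g <- g + grads$taps[["8"]]
    g <- m$children$seg3$backward(g)
    if (!is.null(grads$taps[["4"]])) g <- g + grads$taps[["4"]]
    g <- m$children$seg2$backward(g)
    if (!is.null(grads$taps[["2"]])) g <- g + grads$taps[["2"]]
    m$children$seg1$backward(g)
  }
  m
}

#' Channel widths of a backbone configuration
#'
#' @param config a [BackboneConfig-class].
#' @return list with `stem`, per-stage widths, tap widths and the deepest
#'   width, after applying the width multiplier.
#' @export
backboneChannels <- function(config = backboneConfig()) {
  ch <- scaledChannels(config)
  list(stem = ch$stem, stages = ch$stages,
       taps = c(`2` = ch$stages[[1]], `4` = ch$stages[[2]], `8` = ch$stages[[3]]),
       out = ch$stages[[length(ch$stages)]])
}

#' Analytic feature-map shapes of a backbone
#'
#' Traces spatial sizes through the stem and stages without running any
#' computation; used to verify the output-stride-16 contract (a 480 x 480
#' input yields a 30 x 30 deepest map) and for the comparison against the
#' nominal stride scheme whose deepest map is 1/32 of the input.
#'
#' @param inputSize integer length-2, input (H, W).
#' @param stages list of [StageSpec-class]; defaults to the reference rows.
#' @param stemChannels,widthMultiplier as in [backboneConfig()].
#' @return data.frame with one row per layer group: name, H, W, channels.
#' @export
backboneShapes <- function(inputSize, stages = defaultBackboneStages(),
                           stemChannels = 32L, widthMultiplier = 1) {
  a <- widthMultiplier
  scale1 <- function(c) if (a == 1) as.integer(c) else makeDivisible(c * a)
  H <- inputSize[1]; W <- inputSize[2]
  rows <- data.frame(name = "input", H = H, W = W, channels = 3L,
                     stringsAsFactors = FALSE)
  H <- H %/% 2L; W <- W %/% 2L
  rows <- rbind(rows, data.frame(name = "stem", H = H, W = W,
                                 channels = scale1(stemChannels)))
  for (i in seq_along(stages)) {
    s <- stages[[i]]
    if (s@stride == 2L) { H <- H %/% 2L; W <- W %/% 2L }
    rows <- rbind(rows, data.frame(name = sprintf("stage%d", i), H = H, W = W,
                                   channels = scale1(s@outChannels)))
  }
  rows
}
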