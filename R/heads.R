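# Encoder head (atrous spatial pyramid pooling) and the two decoder styles.

concatChannels <- function(xs) {
  d <- dim(xs[[1]])
  Cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  y <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  off <- 0
  for (x in xs) {
    y[, , off + seq_len(dim(x)[3]), ] <- x
    off <- off + dim(x)[3]
  }
  y
}

splitChannels <- function(dy, Cs) {
  out <- vector("list", length(Cs))
  off <- 0
  for (i in seq_along(Cs)) {
    g <- dy[, , off + seq_len(Cs[i]), , drop = FALSE]
    dim(g) <- c(dim(dy)[1], dim(dy)[2], Cs[i], dim(dy)[4])
    out[[i]] <- g
    off <- off + Cs[i]
  }
  out
}

#' Build the atrous spatial pyramid pooling head
#'
#' Parallel branches over the deepest backbone map: a 1x1 convolution, one
#' 3x3 atrous convolution per rate, and a global-average-pooling branch whose
#' pooled vector is projected and broadcast back to the map size.  Branch
#' outputs are concatenated and projected to `outChannels`; spatial size is
#' preserved.
#'
#' @param inChannels channels of the deepest feature map.
#' @param outChannels projection width (256 in the reference setting).
#' @param rates positive integer atrous rates; `c(6, 12, 18)` is the standard
#'   output-stride-16 choice.
#' @param bnEps,bnMomentum batch-norm settings.
#' @return an ASPP module with `$nBranches` set to `2 + length(rates)`.
#' @export
buildASPP <- function(inChannels, outChannels, rates = c(6L, 12L, 18L),
                      bnEps = 1e-5, bnMomentum = 0.1) {
  if (length(rates) == 0 || any(rates < 1))
    stop("aspp: rates must be a non-empty vector of positive integers")
  m <- csModule("aspp")
  ch <- list(b0 = cbaLayer(inChannels, outChannels, 1L,
                           bnEps = bnEps, bnMomentum = bnMomentum))
  for (i in seq_along(rates)) {
    ch[[sprintf("b%d", i)]] <- cbaLayer(inChannels, outChannels, 3L,
                                        dilation = as.integer(rates[i]),
                                        bnEps = bnEps, bnMomentum = bnMomentum)
  }
  ch$pool <- cbaLayer(inChannels, outChannels, 1L,
                      bnEps = bnEps, bnMomentum = bnMomentum)
  nb <- length(rates) + 2L
  ch$project <- cbaLayer(nb * outChannels, outChannels, 1L,
                         bnEps = bnEps, bnMomentum = bnMomentum)
  m$children <- ch
  m$nBranches <- nb
  m$outChannels <- as.integer(outChannels)
  m$rates <- as.integer(rates)

  m$forward <- function(x, training = TRUE) {
    d <- dim(x)
    m$inDim <- d
    branchNames <- setdiff(names(m$children), "project")
    outs <- vector("list", length(branchNames))
    for (i in seq_along(branchNames)) {
      bn <- branchNames[i]
      if (bn == "pool") {
        s <- cs_gap_fwd(x)                      # C x N
        p <- array(as.vector(s), c(1L, 1L, d[3], d[4]))
        p <- m$children$pool$forward(p, training)
        outs[[i]] <- cs_bilinear_fwd(p, d[1], d[2])
      } else {
        outs[[i]] <- m$children[[bn]]$forward(x, training)
      }
    }
    m$branchNames <- branchNames
    cc <- concatChannels(outs)
    m$children$project$forward(cc, training)
  }
  m$backward <- function(dy) {
    dcc <- m$children$project$backward(dy)
    Cs <- rep(m$outChannels, m$nBranches)
    gs <- splitChannels(dcc, Cs)
    d <- m$inDim
    dx <- 0
    for (i in seq_along(m$branchNames)) {
      bn <- m$branchNames[i]
      if (bn == "pool") {
        gp <- cs_bilinear_bwd(gs[[i]], 1L, 1L)
        gp <- m$children$pool$backward(gp)
        plane <- d[1] * d[2]
        g <- rep(as.vector(gp), each = plane) / plane
        dim(g) <- d
        dx <- dx + g
      } else {
        dx <- dx + m$children[[bn]]$backward(gs[[i]])
      }
    }
    dx
  }
  m
}

#' Build the decoder
#'
#' Two styles. `"layerwise"`: the encoder output is up-sampled 2x and fused
#' (channel concatenation, after a 1x1 reduction of the skip map) with the
#' 1/8-resolution backbone map, refined by 3x3 convolution + batch norm +
#' ReLU, up-sampled 2x and fused with the 1/4 map, refined again, up-sampled
#' and fused with the 1/2 map; after this last fusion two stacked 3x3
#' convolution layers are applied, then a 1x1 classifier, and the logits are
#' up-sampled 2x to input resolution — four 2x up-samplings and three fusions
#' in total.  With `useSE`, an independent squeeze-and-excitation block sits
#' immediately after each of the three fusions.  `"simple"`: the original
#' arrangement — one 4x up-sampling, a single fusion with the 1/4 map, two
#' 3x3 refinement convolutions, classifier, and a final 4x up-sampling.
#'
#' @param style `"layerwise"` or `"simple"`.
#' @param useSE logical; attach squeeze-and-excitation attention after each
#'   fusion (layerwise style).
#' @param inChannels channels arriving from the encoder head.
#' @param tapChannels named integer vector of skip-map widths
#'   (`"2"`, `"4"`, `"8"`); the layerwise style requires all three, the
#'   simple style only `"4"`.
#' @param numClasses classifier width.
#' @param width refinement convolution width.
#' @param reduceChannels width of the 1x1 skip reductions.
#' @param seReduction squeeze-and-excitation bottleneck ratio.
#' @param bnEps,bnMomentum batch-norm settings.
#' @return a decoder module; `$nUpsample`, `$upFactors` and `$nFusions`
#'   record the up-sampling/fusion structure.
#' @export
buildDecoder <- function(style = c("layerwise", "simple"), useSE = FALSE,
                         inChannels, tapChannels, numClasses = 3L,
                         width = 256L, reduceChannels = 48L,
                         seReduction = 16L, bnEps = 1e-5, bnMomentum = 0.1) {
  style <- match.arg(style)
  m <- csModule("decoder")
  m$style <- style
  m$useSE <- useSE

  if (style == "layerwise") {
    need <- c("8", "4", "2")
    if (!all(need %in% names(tapChannels)))
      stop("layerwise decoder requires exactly three tapped maps at factors 8, 4 and 2")
    ch <- list(
      up0 = upsampleLayer(2L),
      reduce8 = cbaLayer(tapChannels[["8"]], reduceChannels, 1L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      refine1 = cbaLayer(inChannels + reduceChannels, width, 3L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      up1 = upsampleLayer(2L),
      reduce4 = cbaLayer(tapChannels[["4"]], reduceChannels, 1L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      refine2 = cbaLayer(width + reduceChannels, width, 3L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      up2 = upsampleLayer(2L),
      reduce2 = cbaLayer(tapChannels[["2"]], reduceChannels, 1L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      stack1 = cbaLayer(width + reduceChannels, width, 3L,
                        bnEps = bnEps, bnMomentum = bnMomentum),
      stack2 = cbaLayer(width, width, 3L,
                        bnEps = bnEps, bnMomentum = bnMomentum),
      classifier = convLayer(width, numClasses, 1L, bias = TRUE),
      upFinal = upsampleLayer(2L))
    if (useSE) {
      ch$se1 <- seLayer(inChannels + reduceChannels, seReduction)
      ch$se2 <- seLayer(width + reduceChannels, seReduction)
      ch$se3 <- seLayer(width + reduceChannels, seReduction)
    }
    m$children <- ch
    m$nUpsample <- 4L
    m$upFactors <- c(2L, 2L, 2L, 2L)
    m$nFusions <- 3L
    m$c1 <- c(inChannels, reduceChannels)
    m$c2 <- c(width, reduceChannels)
    m$c3 <- c(width, reduceChannels)

    m$forward <- function(x, taps, training = TRUE) {
      ch <- m$children
      x <- ch$up0$forward(x, training)
      f <- concatChannels(list(x, ch$reduce8$forward(taps[["8"]], training)))
      if (m$useSE) f <- ch$se1$forward(f, training)
      x <- ch$up1$forward(ch$refine1$forward(f, training), training)
      f <- concatChannels(list(x, ch$reduce4$forward(taps[["4"]], training)))
      if (m$useSE) f <- ch$se2$forward(f, training)
      x <- ch$up2$forward(ch$refine2$forward(f, training), training)
      f <- concatChannels(list(x, ch$reduce2$forward(taps[["2"]], training)))
      if (m$useSE) f <- ch$se3$forward(f, training)
      x <- ch$stack2$forward(ch$stack1$forward(f, training), training)
      ch$upFinal$forward(ch$classifier$forward(x, training), training)
    }
    m$backward <- function(dy) {
      ch <- m$children
      g <- ch$classifier$backward(ch$upFinal$backward(dy))
      g <- ch$stack1$backward(ch$stack2$backward(g))
      if (m$useSE) g <- ch$se3$backward(g)
      gs <- splitChannels(g, m$c3)
      dtap2 <- ch$reduce2$backward(gs[[2]])
      g <- ch$refine2$backward(ch$up2$backward(gs[[1]]))
      if (m$useSE) g <- ch$se2$backward(g)
      gs <- splitChannels(g, m$c2)
      dtap4 <- ch$reduce4$backward(gs[[2]])
      g <- ch$refine1$backward(ch$up1$backward(gs[[1]]))
      if (m$useSE) g <- ch$se1$backward(g)
      gs <- splitChannels(g, m$c1)
      dtap8 <- ch$reduce8$backward(gs[[2]])
      dx <- ch$up0$backward(gs[[1]])
      list(dx = dx, taps = list(`8` = dtap8, `4` = dtap4, `2` = dtap2))
    }
  } else {
    if (!"4" %in% names(tapChannels))
      stop("simple decoder requires the tapped map at factor 4")
    m$children <- list(
      up0 = upsampleLayer(4L),
      reduce4 = cbaLayer(tapChannels[["4"]], reduceChannels, 1L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      refine1 = cbaLayer(inChannels + reduceChannels, width, 3L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      refine2 = cbaLayer(width, width, 3L,
                         bnEps = bnEps, bnMomentum = bnMomentum),
      classifier = convLayer(width, numClasses, 1L, bias = TRUE),
      upFinal = upsampleLayer(4L))
    m$nUpsample <- 2L
    m$upFactors <- c(4L, 4L)
    m$nFusions <- 1L
    m$c1 <- c(inChannels, reduceChannels)
    m$forward <- function(x, taps, training = TRUE) {
      ch <- m$children
      x <- ch$up0$forward(x, training)
      f <- concatChannels(list(x, ch$reduce4$forward(taps[["4"]], training)))
      x <- ch$refine2$forward(ch$refine1$forward(f, training), training)
      ch$upFinal$forward(ch$classifier$forward(x, training), training)
    }
    m$backward <- function(dy) {
      ch <- m$children
      g <- ch$classifier$backward(ch$upFinal$backward(dy))
      g <- ch$refine1$backward(ch$refine2$backward(g))
      gs <- splitChannels(g, m$c1)
      dtap4 <- ch$reduce4$backward(gs[[2]])
      dx <- ch$up0$backward(gs[[1]])
      list(dx = dx, taps = list(`4` = dtap4))
    }
  }
  m
}

#' Stand-alone squeeze-and-excitation block
#'
#' Constructs a squeeze-and-excitation module: global-average-pool squeeze to
#' `1 x 1 x C`, two fully connected layers with hard-swish and hard-sigmoid
#' activations producing one weight in `[0, 1]` per channel, and a per-channel
#' rescale of the input.  Exposed mainly for experimentation and testing; the
#' decoder attaches its own blocks.
#'
#' @param channels number of input channels.
#' @param reduction bottleneck ratio of the excitation layers.
#' @return an SE module (forward maps `H x W x C x N` to the same shape).
#' @export
buildSEBlock <- function(channels, reduction = 16L) {
  if (channels < 1 || reduction < 1)
    stop("se_block: channels and reduction must be positive")
  seLayer(as.integer(channels), as.integer(reduction))
}
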