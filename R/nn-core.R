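# Minimal define-by-structure neural-network layer framework.
#
# A module is an environment with a $forward(x, training) and $backward(dy)
# method; layers cache whatever the backward pass needs on the module itself.
# Parameters are environments with $v (value), $g (gradient accumulator) and
# $m (SGD momentum buffer) so that optimiser updates have reference semantics.
# Composite modules keep their sub-modules in $children; collectParams() walks
# the tree and returns a flat named list, the names encoding the module path
# so that two structurally aligned networks can share weights by name.

newParam <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- value * 0
  e$m <- value * 0
  class(e) <- "csParam"
  e
}

csModule <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$children <- list()
  class(m) <- c(paste0("cs_", type), "csModule")
  m
}

collectParams <- function(mod, prefix = "") {
  out <- list()
  if (length(mod$params)) {
    nm <- paste0(prefix, names(mod$params))
    out <- mod$params
    names(out) <- nm
  }
  for (cn in names(mod$children)) {
    out <- c(out, collectParams(mod$children[[cn]], paste0(prefix, cn, ".")))
  }
  out
}

collectBNStats <- function(mod, prefix = "") {
  out <- list()
  if (identical(mod$type, "bn")) {
    out[[paste0(prefix, "stats")]] <- list(rmean = mod$rmean, rvar = mod$rvar)
  }
  for (cn in names(mod$children)) {
    out <- c(out, collectBNStats(mod$children[[cn]], paste0(prefix, cn, ".")))
  }
  out
}

restoreBNStats <- function(mod, stats, prefix = "") {
  if (identical(mod$type, "bn")) {
    s <- stats[[paste0(prefix, "stats")]]
    if (!is.null(s)) { mod$rmean <- s$rmean; mod$rvar <- s$rvar }
  }
  for (cn in names(mod$children)) {
    restoreBNStats(mod$children[[cn]], stats, paste0(prefix, cn, "."))
  }
  invisible(mod)
}

# ---- layers -----------------------------------------------------------------

convLayer <- function(inC, outC, k = 3L, stride = 1L, dilation = 1L,
                      bias = FALSE, needInputGrad = TRUE) {
  m <- csModule("conv")
  m$stride <- as.integer(stride)
  m$dilation <- as.integer(dilation)
  m$pad <- as.integer(dilation * ((k - 1) %/% 2))
  m$bias <- bias
  m$needInputGrad <- needInputGrad
  fanOut <- k * k * outC
  m$params$w <- newParam(array(stats::rnorm(k * k * inC * outC, sd = sqrt(2 / fanOut)),
                               dim = c(k, k, inC, outC)))
  if (bias) m$params$b <- newParam(numeric(outC))
  m$forward <- function(x, training = TRUE) {
    m$x <- x
    cs_conv2d_fwd(x, m$params$w$v, if (m$bias) m$params$b$v else numeric(0),
                  m$stride, m$pad, m$dilation)
  }
  m$backward <- function(dy) {
    r <- cs_conv2d_bwd(m$x, m$params$w$v, dy, m$stride, m$pad, m$dilation,
                       m$needInputGrad, m$bias)
    m$params$w$g <- m$params$w$g + r$dw
    if (m$bias) m$params$b$g <- m$params$b$g + r$db
    r$dx
  }
  m
}

dwconvLayer <- function(C, k = 3L, stride = 1L, dilation = 1L) {
  m <- csModule("dwconv")
  m$stride <- as.integer(stride)
  m$dilation <- as.integer(dilation)
  m$pad <- as.integer(dilation * ((k - 1) %/% 2))
  fanOut <- k * k
  m$params$w <- newParam(array(stats::rnorm(k * k * C, sd = sqrt(2 / fanOut)),
                               dim = c(k, k, C)))
  m$forward <- function(x, training = TRUE) {
    m$x <- x
    cs_dwconv_fwd(x, m$params$w$v, m$stride, m$pad, m$dilation)
  }
  m$backward <- function(dy) {
    r <- cs_dwconv_bwd(m$x, m$params$w$v, dy, m$stride, m$pad, m$dilation)
    m$params$w$g <- m$params$w$g + r$dw
    r$dx
  }
  m
}

bnLayer <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- csModule("bn")
  m$eps <- eps
  m$momentum <- momentum
  m$rmean <- numeric(C)
  m$rvar <- rep(1, C)
  m$params$gamma <- newParam(rep(1, C))
  m$params$beta <- newParam(numeric(C))
  m$forward <- function(x, training = TRUE) {
    r <- cs_bn_fwd(x, m$params$gamma$v, m$params$beta$v, m$rmean, m$rvar,
                   m$momentum, m$eps, training)
    m$lastTraining <- training
    m$x <- x
    m$mean <- r$mean
    m$invstd <- r$invstd
    if (training) {
      m$rmean <- r$rmean
      m$rvar <- r$rvar
    }
    r$y
  }
  m$backward <- function(dy) {
    if (isTRUE(m$lastTraining)) {
      r <- cs_bn_bwd(m$x, m$params$gamma$v, dy, m$mean, m$invstd)
      m$params$gamma$g <- m$params$gamma$g + r$dgamma
      m$params$beta$g <- m$params$beta$g + r$dbeta
      return(r$dx)
    }
    # inference mode: running statistics are constants, so the map is a
    # per-channel affine transform (used e.g. by receptive-field probes)
    d <- dim(dy)
    plane <- d[1] * d[2]
    scale <- m$params$gamma$v * m$invstd
    g <- dy * rep(rep(scale, each = plane), times = d[4])
    dim(g) <- d
    g
  }
  m
}

#' Hard-swish activation
#'
#' `x * min(max(x + 3, 0), 6) / 6`, the piecewise-linear approximation of
#' swish used inside the squeeze-and-excitation block.
#' @param x numeric vector or array.
#' @return same shape as `x`.
#' @export
hardSwish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

#' Hard-sigmoid activation
#'
#' `min(max(x + 3, 0), 6) / 6`; saturates at 0 for `x <= -3` and at 1 for
#' `x >= 3`, which bounds excitation weights to `[0, 1]`.
#' @param x numeric vector or array.
#' @return same shape as `x`.
#' @export
hardSigmoid <- function(x) pmin(pmax(x + 3, 0), 6) / 6

hardSwishGrad <- function(x) ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
hardSigmoidGrad <- function(x) ifelse(x > -3 & x < 3, 1 / 6, 0)

actLayer <- function(kind = c("relu", "relu6", "hswish", "hsigmoid")) {
  kind <- match.arg(kind)
  m <- csModule("act")
  m$kind <- kind
  m$forward <- function(x, training = TRUE) {
    m$x <- x
    y <- switch(kind,
      relu = pmax(x, 0),
      relu6 = pmin(pmax(x, 0), 6),
      hswish = hardSwish(x),
      hsigmoid = hardSigmoid(x))
    dim(y) <- dim(x)
    y
  }
  m$backward <- function(dy) {
    g <- switch(kind,
      relu = dy * (m$x > 0),
      relu6 = dy * (m$x > 0 & m$x < 6),
      hswish = dy * hardSwishGrad(m$x),
      hsigmoid = dy * hardSigmoidGrad(m$x))
    dim(g) <- dim(dy)
    g
  }
  m
}

upsampleLayer <- function(factor = 2L) {
  m <- csModule("upsample")
  m$factor <- as.integer(factor)
  m$forward <- function(x, training = TRUE) {
    d <- dim(x)
    m$inH <- d[1]; m$inW <- d[2]
    cs_bilinear_fwd(x, d[1] * m$factor, d[2] * m$factor)
  }
  m$backward <- function(dy) cs_bilinear_bwd(dy, m$inH, m$inW)
  m
}

seqLayer <- function(mods) {
  m <- csModule("seq")
  names(mods) <- sprintf("l%02d", seq_along(mods))
  m$children <- mods
  m$forward <- function(x, training = TRUE) {
    for (ch in m$children) x <- ch$forward(x, training)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}

# conv + BN + activation, the standard composite unit.
cbaLayer <- function(inC, outC, k = 3L, stride = 1L, dilation = 1L,
                     act = "relu", bnEps = 1e-5, bnMomentum = 0.1,
                     needInputGrad = TRUE) {
  seqLayer(list(
    convLayer(inC, outC, k, stride, dilation, bias = FALSE,
              needInputGrad = needInputGrad),
    bnLayer(outC, bnEps, bnMomentum),
    actLayer(act)))
}

# ---- squeeze-and-excitation -------------------------------------------------

# Channel attention: squeeze = global average pool to 1x1xC, excitation = two
# fully connected layers (H-Swish then H-Sigmoid), scale = per-channel
# multiply.  `pinned = TRUE` forces every excitation weight to exactly 1,
# turning the block into an identity (used by equivalence checks).
seLayer <- function(C, reduction = 16L) {
  m <- csModule("se")
  hidden <- max(4L, as.integer(round(C / reduction)))
  m$C <- as.integer(C)
  m$hidden <- hidden
  m$pinned <- FALSE
  m$params$w1 <- newParam(matrix(stats::rnorm(hidden * C, sd = sqrt(2 / C)), hidden, C))
  m$params$b1 <- newParam(numeric(hidden))
  m$params$w2 <- newParam(matrix(stats::rnorm(C * hidden, sd = sqrt(2 / hidden)), C, hidden))
  m$params$b2 <- newParam(numeric(C))
  m$forward <- function(x, training = TRUE) {
    if (m$pinned) { m$wasPinned <- TRUE; return(x) }
    m$wasPinned <- FALSE
    d <- dim(x)
    if (d[3] != m$C)
      stop(sprintf("se_block: feature map has %d channels, block expects %d", d[3], m$C))
    m$x <- x
    m$s <- cs_gap_fwd(x)                       # C x N
    m$a1 <- m$params$w1$v %*% m$s + m$params$b1$v
    m$h1 <- hardSwish(m$a1)
    m$a2 <- m$params$w2$v %*% m$h1 + m$params$b2$v
    m$wgt <- hardSigmoid(m$a2)                 # C x N, in [0, 1]
    plane <- d[1] * d[2]
    y <- x * rep(as.vector(m$wgt), each = plane)
    dim(y) <- d
    y
  }
  m$backward <- function(dy) {
    if (isTRUE(m$wasPinned)) return(dy)
    d <- dim(m$x)
    plane <- d[1] * d[2]
    wrep <- rep(as.vector(m$wgt), each = plane)
    dwgt <- cs_gap_fwd(dy * m$x) * plane       # sum over plane
    dx <- dy * wrep
    da2 <- dwgt * hardSigmoidGrad(m$a2)
    m$params$w2$g <- m$params$w2$g + da2 %*% t(m$h1)
    m$params$b2$g <- m$params$b2$g + rowSums(da2)
    dh1 <- t(m$params$w2$v) %*% da2
    da1 <- dh1 * hardSwishGrad(m$a1)
    m$params$w1$g <- m$params$w1$g + da1 %*% t(m$s)
    m$params$b1$g <- m$params$b1$g + rowSums(da1)
    ds <- t(m$params$w1$v) %*% da1             # C x N
    dx <- dx + rep(as.vector(ds), each = plane) / plane
    dim(dx) <- d
    dx
  }
  m
}

# ---- optimiser --------------------------------------------------------------

zeroGrads <- function(params) {
  for (p in params) p$g <- p$g * 0
  invisible(NULL)
}

sgdStep <- function(params, lr, momentum = 0.9, weightDecay = 0) {
  for (p in params) {
    g <- p$g
    if (weightDecay > 0) g <- g + weightDecay * p$v
    p$m <- momentum * p$m + g
    p$v <- p$v - lr * p$m
  }
  invisible(NULL)
}
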