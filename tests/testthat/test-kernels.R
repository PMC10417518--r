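# Finite-difference verification of every compiled forward/backward pair.
# The analytic gradients come from the C++ kernels; the numeric side is
# central differences through the forward pass only, so the two routes are
# independent.

test_that("convolution gradients match finite differences for stride and dilation", {
  set.seed(4)
  H <- 6L; W <- 5L; C <- 3L; Co <- 4L; N <- 2L
  x <- array(rnorm(H * W * C * N), c(H, W, C, N))
  w <- array(rnorm(3 * 3 * C * Co) * 0.3, c(3, 3, C, Co))
  b <- rnorm(Co)
  for (cfg in list(list(s = 1L, d = 1L), list(s = 2L, d = 1L), list(s = 1L, d = 2L))) {
    s <- cfg$s; d <- cfg$d; p <- d * 1L
    y <- cs_conv2d_fwd(x, w, b, s, p, d)
    dy <- array(rnorm(length(y)), dim(y))
    r <- cs_conv2d_bwd(x, w, dy, s, p, d, TRUE, TRUE)

    lossX <- function(xx) sum(cs_conv2d_fwd(xx, w, b, s, p, d) * dy)
    ixs <- sample(length(x), 6)
    expect_equal(r$dx[ixs], numericGrad(lossX, x, ixs), tolerance = 1e-6)

    lossW <- function(ww) sum(cs_conv2d_fwd(x, ww, b, s, p, d) * dy)
    ixw <- sample(length(w), 6)
    expect_equal(r$dw[ixw], numericGrad(lossW, w, ixw), tolerance = 1e-6)
    expect_equal(as.numeric(r$db), apply(dy, 3, sum), tolerance = 1e-8)
  }
})

test_that("1x1 convolution fast path agrees with the im2col path", {
  set.seed(5)
  x <- array(rnorm(8 * 7 * 5 * 2), c(8, 7, 5, 2))
  w1 <- array(rnorm(1 * 1 * 5 * 3), c(1, 1, 5, 3))
  # embed the 1x1 kernel in a 3x3 kernel of zeros: same linear map
  w3 <- array(0, c(3, 3, 5, 3)); w3[2, 2, , ] <- w1[1, 1, , ]
  y1 <- cs_conv2d_fwd(x, w1, numeric(0), 1L, 0L, 1L)
  y3 <- cs_conv2d_fwd(x, w3, numeric(0), 1L, 1L, 1L)
  expect_equal(y1, y3, tolerance = 1e-12)
})

test_that("depthwise convolution gradients match finite differences", {
  set.seed(6)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  w <- array(rnorm(3 * 3 * 3) * 0.3, c(3, 3, 3))
  for (cfg in list(list(s = 1L, d = 2L), list(s = 2L, d = 1L))) {
    p <- cfg$d
    y <- cs_dwconv_fwd(x, w, cfg$s, p, cfg$d)
    dy <- array(rnorm(length(y)), dim(y))
    r <- cs_dwconv_bwd(x, w, dy, cfg$s, p, cfg$d)
    lossX <- function(xx) sum(cs_dwconv_fwd(xx, w, cfg$s, p, cfg$d) * dy)
    ixs <- sample(length(x), 6)
    expect_equal(r$dx[ixs], numericGrad(lossX, x, ixs), tolerance = 1e-6)
    lossW <- function(ww) sum(cs_dwconv_fwd(x, ww, cfg$s, p, cfg$d) * dy)
    ixw <- seq_along(w)
    expect_equal(as.numeric(r$dw[ixw]), numericGrad(lossW, w, ixw), tolerance = 1e-6)
  }
})

test_that("batch-norm training statistics, output and gradients are correct", {
  set.seed(7)
  C <- 3L
  x <- array(rnorm(5 * 4 * C * 2, mean = 2, sd = 3), c(5, 4, C, 2))
  gamma <- runif(C, 0.5, 1.5); beta <- rnorm(C)
  r <- cs_bn_fwd(x, gamma, beta, numeric(C), rep(1, C), 0.1, 1e-5, TRUE)
  for (cl in seq_len(C)) {
    v <- as.vector(x[, , cl, ])
    expect_equal(r$mean[cl], mean(v), tolerance = 1e-10)
    yv <- as.vector(r$y[, , cl, ])
    expect_equal(mean(yv), beta[cl], tolerance = 1e-8)
    expect_equal(sd(yv) * sqrt((length(yv) - 1) / length(yv)), gamma[cl],
                 tolerance = 1e-4)
    # running stats blend with the unbiased batch variance
    expect_equal(r$rvar[cl], 0.9 * 1 + 0.1 * var(v), tolerance = 1e-8)
  }
  dy <- array(rnorm(length(x)), dim(x))
  g <- cs_bn_bwd(x, gamma, dy, r$mean, r$invstd)
  loss <- function(xx) sum(cs_bn_fwd(xx, gamma, beta, numeric(C), rep(1, C),
                                     0.1, 1e-5, TRUE)$y * dy)
  ixs <- sample(length(x), 8)
  expect_equal(g$dx[ixs], numericGrad(loss, x, ixs), tolerance = 1e-5)
})

test_that("bilinear resize is exact on constants and its backward is the transpose", {
  xc <- array(3.7, c(4, 6, 2, 1))
  expect_equal(as.vector(cs_bilinear_fwd(xc, 8, 12)), rep(3.7, 8 * 12 * 2),
               tolerance = 1e-12)
  set.seed(8)
  x <- array(rnorm(5 * 4 * 2 * 2), c(5, 4, 2, 2))
  y <- cs_bilinear_fwd(x, 10, 8)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- cs_bilinear_bwd(dy, 5L, 4L)
  # <dy, F x> == <F^T dy, x> for the linear map F
  expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-8)
  ixs <- sample(length(x), 6)
  loss <- function(xx) sum(cs_bilinear_fwd(xx, 10, 8) * dy)
  expect_equal(dx[ixs], numericGrad(loss, x, ixs), tolerance = 1e-6)
})

test_that("softmax cross-entropy loss and gradient are consistent and ignore labels", {
  set.seed(9)
  lg <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  tg <- array(sample(0:2, 40, TRUE), c(4, 5, 2))
  tg[1, 1, 1] <- -1L
  storage.mode(tg) <- "integer"
  r <- cs_softmax_ce(lg, tg)
  ixs <- sample(length(lg), 8)
  num <- numericGrad(function(ll) cs_softmax_ce(ll, tg)$loss, lg, ixs, eps = 1e-6)
  expect_equal(r$dx[ixs], num, tolerance = 1e-4)
  # ignored pixel contributes no gradient
  expect_equal(r$dx[1, 1, , 1], rep(0, 3))
  # perfect confident prediction has near-zero loss
  one <- array(0L, c(1, 1, 1)); one[1] <- tg[1, 2, 1]
  lgp <- array(c(-50, -50, -50), c(1, 1, 3, 1)); lgp[1, 1, one[1] + 1, 1] <- 50
  expect_lt(cs_softmax_ce(lgp, one)$loss, 1e-10)
})

test_that("channel argmax picks the maximal class and breaks ties low", {
  x <- array(0, c(2, 2, 3, 1))
  x[1, 1, , 1] <- c(0.1, 0.9, 0.2)
  x[1, 2, , 1] <- c(0.5, 0.5, 0.4)   # tie -> class 0
  x[2, 1, , 1] <- c(0, 0, 1)
  lab <- cs_channel_argmax(x)
  expect_equal(lab[1, 1, 1], 1L)
  expect_equal(lab[1, 2, 1], 0L)
  expect_equal(lab[2, 1, 1], 2L)
})
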