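# Shared fixtures: compact network settings for fast structural tests, a
# brute-force metrics oracle independent of the confusion-matrix code path,
# and small scene builders.

tinyNetworkOptions <- function(seed = 1L) {
  networkOptions(widthMultiplier = 0.1, decoderChannels = 16L,
                 reduceChannels = 8L, asppChannels = 32L,
                 asppRates = c(1L, 2L, 3L), seReduction = 4L, seed = seed)
}

randomImageBatch <- function(H, W, N = 1L, seed = 1L) {
  withr::with_seed(seed, array(stats::runif(H * W * 3 * N), c(H, W, 3L, N)))
}

randomMask <- function(H, W, nc = 3L, seed = 1L) {
  withr::with_seed(seed,
    matrix(sample(0:(nc - 1L), H * W, replace = TRUE), H, W))
}

# Brute-force per-pixel counting oracle: no confusion matrix, just direct
# set arithmetic over the two masks.
oracleMetrics <- function(pred, truth, nc) {
  pa <- mean(pred == truth)
  cpa <- vapply(0:(nc - 1L), function(cl) {
    pp <- sum(pred == cl)
    if (pp == 0) NA_real_ else sum(pred == cl & truth == cl) / pp
  }, numeric(1))
  iou <- vapply(0:(nc - 1L), function(cl) {
    un <- sum(pred == cl | truth == cl)
    if (un == 0) NA_real_ else sum(pred == cl & truth == cl) / un
  }, numeric(1))
  list(pa = pa, cpa = cpa, iou = iou,
       mpa = mean(cpa, na.rm = TRUE), miou = mean(iou, na.rm = TRUE))
}

# Scenes whose classes are pure colour cues (cow = red blobs, beef = green
# blobs on a dark background): linearly separable, the "can this
# architecture segment at all" dataset.
colorCodedScene <- function(size = 96L, seed = 1L) {
  rec <- sceneRecipe(canvasSize = c(size, size), nAnimals = c(1L, 2L),
                     occluderRate = 0, animalScale = 0.26, seed = seed)
  sc <- generateScene(rec)
  img <- array(0.1, dim(sc@image))
  for (cl in 1:2) {
    sel <- sc@mask == cl
    plane <- img[, , cl]
    plane[sel] <- 0.95
    img[, , cl] <- plane
  }
  labeledScene(img, sc@mask, sprintf("colorcoded-%d", seed))
}

numericGrad <- function(f, x, ixs, eps = 1e-5) {
  vapply(ixs, function(ix) {
    xp <- x; xp[ix] <- xp[ix] + eps
    xm <- x; xm[ix] <- xm[ix] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
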