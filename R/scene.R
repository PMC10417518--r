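#' A labelled scene
#'
#' An RGB image paired with its per-pixel class mask and bookkeeping
#' metadata.  Labels are 0 = background, 1 = cow, 2 = beef by default.
#'
#' @slot image numeric `H x W x 3` array with values in `[0, 1]`.
#' @slot mask integer `H x W` matrix of class labels.
#' @slot sceneId character identifier.
#' @slot fogged logical; has the fog operator been applied.
#' @slot fogStrength numeric, the fog attenuation coefficient (0 = clear).
#' @export
setClass("LabeledScene", representation(
  image = "array", mask = "matrix", sceneId = "character",
  fogged = "logical", fogStrength = "numeric"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "image must be H x W x 3")
    if (!identical(dim(object@mask), d[1:2]))
      msg <- c(msg, "image and mask spatial dimensions disagree")
    if (length(object@mask) && min(object@mask) < 0L)
      msg <- c(msg, "mask labels must be non-negative")
    if (object@fogStrength < 0) msg <- c(msg, "fogStrength must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param image,mask,sceneId,fogged,fogStrength see slots.
#' @rdname LabeledScene-class
#' @export
labeledScene <- function(image, mask, sceneId = "scene",
                         fogged = FALSE, fogStrength = 0) {
  storage.mode(mask) <- "integer"
  new("LabeledScene", image = image, mask = mask, sceneId = sceneId,
      fogged = fogged, fogStrength = fogStrength)
}

setMethod("show", "LabeledScene", function(object) {
  d <- dim(object@image)
  lab <- sort(unique(as.integer(object@mask)))
  cat(sprintf("LabeledScene '%s': %d x %d, labels {%s}%s\n", object@sceneId,
              d[1], d[2], paste(lab, collapse = ","),
              if (object@fogged) sprintf(", fogged (beta = %.2f)",
                                         object@fogStrength) else ""))
})

#' Synthetic scene recipe
#'
#' Parameters of the procedural generator that emulates multi-animal farm
#' scenes:
#' a textured pasture background, one or more animals of two visually
#' distinct classes (cows: high-contrast black-and-white patches; beef:
#' uniform dark warm-brown coat), and optional railing occluders drawn over
#' the animals with the occluded pixels relabelled as background.  An
#' identical recipe and seed reproduces the scene bit for bit.
#'
#' @slot canvasSize integer (H, W), at least 64 x 64.
#' @slot nAnimals integer range (min, max) of animals per scene.
#' @slot classMix numeric in `[0, 1]`, probability an animal is a cow.
#' @slot occluderRate numeric, expected railing occluders per scene.
#' @slot animalScale numeric, animal semi-major axis as a fraction of the
#'   short canvas side.
#' @slot seed integer seed.
#' @export
setClass("SceneRecipe", representation(
  canvasSize = "integer", nAnimals = "integer", classMix = "numeric",
  occluderRate = "numeric", animalScale = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@canvasSize < 64L)) msg <- c(msg, "canvas must be >= 64 x 64")
    if (object@nAnimals[1] < 0L || object@nAnimals[2] < object@nAnimals[1])
      msg <- c(msg, "nAnimals must be a non-negative (min, max) range")
    if (object@classMix < 0 || object@classMix > 1)
      msg <- c(msg, "classMix must be in [0, 1]")
    if (object@occluderRate < 0) msg <- c(msg, "occluderRate must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param canvasSize,nAnimals,classMix,occluderRate,animalScale,seed see slots.
#' @rdname SceneRecipe-class
#' @export
sceneRecipe <- function(canvasSize = c(96L, 96L), nAnimals = c(1L, 4L),
                        classMix = 0.5, occluderRate = 0.5,
                        animalScale = 0.16, seed = 1L) {
  if (length(nAnimals) == 1L) nAnimals <- c(nAnimals, nAnimals)
  new("SceneRecipe", canvasSize = as.integer(canvasSize),
      nAnimals = as.integer(nAnimals), classMix = classMix,
      occluderRate = occluderRate, animalScale = animalScale,
      seed = as.integer(seed))
}

setMethod("show", "SceneRecipe", function(object) {
  cat(sprintf(
    "SceneRecipe: %d x %d, %d-%d animals (P(cow) = %.2f), occluder rate %.2f, seed %d\n",
    object@canvasSize[1], object@canvasSize[2], object@nAnimals[1],
    object@nAnimals[2], object@classMix, object@occluderRate, object@seed))
})

# Low-frequency value noise: coarse uniform grid bilinearly upsampled.
lowFreqNoise <- function(H, W, cells = 6L) {
  g <- array(stats::runif(cells * cells), c(cells, cells, 1L, 1L))
  array(cs_bilinear_fwd(g, H, W), c(H, W))
}

#' Generate one synthetic scene
#'
#' @param recipe a [SceneRecipe-class].
#' @param sceneId identifier for the generated scene.
#' @return a [LabeledScene-class] with an exact mask.
#' @examples
#' sc <- generateScene(sceneRecipe(seed = 11))
#' table(sc@mask)
#' @export
generateScene <- function(recipe, sceneId = NULL) {
  validObject(recipe)
  if (is.null(sceneId)) sceneId <- sprintf("synthetic-%d", recipe@seed)
  withSeed(recipe@seed, {
    H <- recipe@canvasSize[1]; W <- recipe@canvasSize[2]

    # pasture background: low-frequency green/brown mixture plus fine grain
    n1 <- lowFreqNoise(H, W, 6L)
    img <- array(0, c(H, W, 3L))
    img[, , 1] <- 0.30 + 0.18 * n1
    img[, , 2] <- 0.42 + 0.16 * n1
    img[, , 3] <- 0.16 + 0.10 * n1
    img <- img + array(stats::rnorm(H * W * 3, sd = 0.02), c(H, W, 3L))
    mask <- matrix(0L, H, W)

    rowIdx <- matrix(seq_len(H) - 0.5, H, W)
    colIdx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)

    nA <- if (recipe@nAnimals[2] > recipe@nAnimals[1])
      sample(recipe@nAnimals[1]:recipe@nAnimals[2], 1L) else recipe@nAnimals[1]
    placed <- list()
    for (k in seq_len(nA)) {
      a <- stats::runif(1, 0.75, 1.25) * recipe@animalScale * min(H, W)
      b <- a * stats::runif(1, 0.50, 0.70)
      theta <- stats::runif(1, 0, pi)
      ok <- FALSE
      for (try in 1:90) {
        if (try %% 15L == 0L) { a <- 0.85 * a; b <- 0.85 * b }
        margin <- min(1.6 * a, 0.45 * min(H, W))
        cy <- stats::runif(1, margin, H - margin)
        cx <- stats::runif(1, margin, W - margin)
        clear <- TRUE
        for (p in placed)
          if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) < 1.35 * (a + p$a)) {
            clear <- FALSE; break
          }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) next                      # canvas too crowded; place fewer
      cls <- if (stats::runif(1) < recipe@classMix) 1L else 2L

      dy <- rowIdx - cy; dx <- colIdx - cx
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      body <- (u / a)^2 + (v / b)^2 <= 1
      hx <- cx + 1.05 * a * cos(theta); hy <- cy + 1.05 * a * sin(theta)
      head <- (rowIdx - hy)^2 + (colIdx - hx)^2 <= (0.38 * a)^2
      region <- body | head
      if (!any(region)) next

      if (cls == 1L) {
        # cow: white coat with black low-frequency patches
        patch <- lowFreqNoise(H, W, max(4L, as.integer(min(H, W) / 18)))
        coat <- ifelse(patch > 0.55, 0.07, 0.93)
        for (chn in 1:3) {
          plane <- img[, , chn]
          plane[region] <- coat[region] +
            stats::rnorm(sum(region), sd = 0.02)
          img[, , chn] <- plane
        }
      } else {
        # beef: uniform dark warm-brown coat with per-animal jitter
        jit <- stats::runif(1, 0.85, 1.15)
        base <- c(0.36, 0.20, 0.12) * jit
        for (chn in 1:3) {
          plane <- img[, , chn]
          plane[region] <- base[chn] + stats::rnorm(sum(region), sd = 0.015)
          img[, , chn] <- plane
        }
      }
      mask[region] <- cls
      placed[[length(placed) + 1L]] <- list(cy = cy, cx = cx, a = a)
    }

    # railing occluders: straight bars drawn over everything; occluded
    # animal pixels revert to background in the mask
    nBars <- stats::rpois(1, recipe@occluderRate)
    for (k in seq_len(nBars)) {
      thick <- max(2L, as.integer(round(0.03 * min(H, W))))
      shade <- stats::runif(1, 0.85, 1.1)
      barCol <- c(0.52, 0.47, 0.40) * shade
      if (stats::runif(1) < 0.5) {
        r0 <- sample(seq_len(H - thick), 1L)
        rows <- r0:(r0 + thick - 1L)
        for (chn in 1:3)
          img[rows, , chn] <- barCol[chn] +
            stats::rnorm(length(rows) * W, sd = 0.02)
        mask[rows, ] <- 0L
      } else {
        c0 <- sample(seq_len(W - thick), 1L)
        cols <- c0:(c0 + thick - 1L)
        for (chn in 1:3)
          img[, cols, chn] <- barCol[chn] +
            stats::rnorm(H * length(cols), sd = 0.02)
        mask[, cols] <- 0L
      }
    }

    img[img < 0] <- 0; img[img > 1] <- 1
    labeledScene(img, mask, sceneId)
  })
}

#' Generate a batch of scenes
#'
#' Each scene gets its own seed derived deterministically from the recipe
#' seed and its index, so the whole set is reproducible and individual scenes
#' are independent of how many are generated.
#'
#' @param recipe a [SceneRecipe-class].
#' @param n number of scenes.
#' @param prefix scene-id prefix.
#' @return list of [LabeledScene-class].
#' @export
generateScenes <- function(recipe, n, prefix = "synthetic") {
  lapply(seq_len(n), function(i) {
    r <- recipe
    r@seed <- deriveSeed(recipe@seed, sprintf("scene%06d", i))
    generateScene(r, sceneId = sprintf("%s-%04d", prefix, i))
  })
}
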