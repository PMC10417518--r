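# Synthetic fog degradation via the atmospheric-scattering model.

# Smooth pseudo-depth field: far at the top of the frame, near at the
# bottom, plus seeded low-frequency variation; strictly positive.
pseudoDepth <- function(H, W, seed) {
  withSeed(seed, {
    vert <- matrix(rep(seq(1.45, 0.50, length.out = H), W), H, W)
    d <- vert + 0.25 * (lowFreqNoise(H, W, 5L) - 0.5)
    d[d < 0.05] <- 0.05
    d
  })
}

#' Apply synthetic fog to a scene
#'
#' Composites the scene with the atmospheric-scattering model
#' `I = J * t + A * (1 - t)` where the transmission is `t = exp(-beta * d)`,
#' `d` a smooth pseudo-depth field (vertical gradient plus seeded
#' low-frequency noise) and `A` the airlight colour.  The mask is never
#' altered.  `beta = 0` returns the image unchanged; as `beta` grows every
#' pixel converges to the airlight.
#'
#' @param scene a [LabeledScene-class].
#' @param strength attenuation coefficient `beta >= 0`.
#' @param airlight RGB airlight colour in `[0, 1]`.
#' @param seed seed for the depth field's low-frequency component.
#' @return a fogged [LabeledScene-class] (`fogged = TRUE`,
#'   `fogStrength = strength`).
#' @examples
#' sc <- generateScene(sceneRecipe(seed = 5))
#' foggy <- applyFog(sc, strength = 1.5)
#' identical(foggy@mask, sc@mask)   # TRUE
#' @export
applyFog <- function(scene, strength, airlight = c(0.90, 0.92, 0.95),
                     seed = 1L) {
  if (strength < 0) stop("fog strength must be >= 0")
  d <- dim(scene@image)
  t <- exp(-strength * pseudoDepth(d[1], d[2], seed))
  img <- scene@image
  for (chn in 1:3)
    img[, , chn] <- img[, , chn] * t + airlight[chn] * (1 - t)
  new("LabeledScene", image = img, mask = scene@mask,
      sceneId = scene@sceneId, fogged = TRUE, fogStrength = strength)
}

#' Fog evaluation protocol for a test set
#'
#' Deterministically selects `round(fraction * N)` scenes and fogs each with
#' an attenuation coefficient drawn uniformly from `betaRange` under the
#' seed, reproducing the protocol of fogging half the test set.  Besides the
#' mixed set, the all-clear ("sunny") and all-fogged ("foggy") companion
#' test sets are returned, so a model can be scored under the three
#' conditions.
#'
#' @param scenes non-empty list of [LabeledScene-class].
#' @param fraction fraction of scenes to fog in the mixed set (default 0.5).
#' @param betaRange length-2 range of fog strengths.
#' @param seed integer seed controlling selection and strengths.
#' @param mode `"replace"` (fogged copies replace the originals in the mixed
#'   set) or `"augment"` (fogged copies are appended, keeping the originals).
#' @return list with elements `mixed`, `sunny`, `foggy` (lists of scenes)
#'   and `foggedIds` (scene ids selected for fogging in the mixed set).
#' @export
fogTestProtocol <- function(scenes, fraction = 0.5, betaRange = c(0.8, 2.0),
                            seed = 1L, mode = c("replace", "augment")) {
  mode <- match.arg(mode)
  if (!length(scenes)) stop("fog protocol: test set is empty")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  N <- length(scenes)
  k <- round(fraction * N)
  sel <- withSeed(seed, {
    idx <- if (k > 0) sample.int(N, k) else integer(0)
    betas <- stats::runif(N, betaRange[1], betaRange[2])
    list(idx = idx, betas = betas)
  })
  fogOne <- function(i) applyFog(scenes[[i]], sel$betas[i],
                                 seed = deriveSeed(seed, i))
  mixed <- scenes
  if (mode == "replace") {
    for (i in sel$idx) mixed[[i]] <- fogOne(i)
  } else {
    mixed <- c(mixed, lapply(sel$idx, fogOne))
  }
  foggy <- lapply(seq_len(N), fogOne)
  list(mixed = mixed, sunny = scenes, foggy = foggy,
       foggedIds = vapply(scenes[sel$idx], function(s) s@sceneId, ""))
}
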