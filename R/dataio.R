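# Annotation ingestion, mask encoding and dataset bookkeeping.

#' Class display palette
#'
#' Colours used for mask encoding and prediction overlays: background black,
#' cow red, beef green (the conventional display colours for this task),
#' then blue/yellow/magenta/cyan for any further classes.
#'
#' @param n number of classes.
#' @return `n x 3` matrix of RGB values in `[0, 1]`.
#' @export
classPalette <- function(n = 3L) {
  pal <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  if (n > nrow(pal)) stop("palette supports at most ", nrow(pal), " classes")
  pal[seq_len(n), , drop = FALSE]
}

# Even-odd scanline polygon fill on pixel centres.  Coordinates follow the
# annotation convention: x along width, y along height, origin at the
# top-left image corner; the pixel in row r, column c (1-based) has centre
# (c - 0.5, r - 0.5).  A boundary pixel is filled when its centre lies
# inside the polygon.
fillPolygon <- function(mask, xs, ys, value) {
  H <- nrow(mask); W <- ncol(mask)
  nv <- length(xs)
  rlo <- max(1L, as.integer(floor(min(ys) + 0.5)) + 1L - 1L)
  rhi <- min(H, as.integer(ceiling(max(ys) + 0.5)))
  if (rlo > rhi) return(mask)
  for (r in rlo:rhi) {
    yc <- r - 0.5
    cuts <- numeric(0)
    j <- nv
    for (i in seq_len(nv)) {
      y1 <- ys[j]; y2 <- ys[i]
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        x1 <- xs[j]; x2 <- xs[i]
        cuts <- c(cuts, x1 + (yc - y1) * (x2 - x1) / (y2 - y1))
      }
      j <- i
    }
    if (length(cuts) >= 2) {
      cuts <- sort(cuts)
      for (k in seq(1, length(cuts) - 1, by = 2)) {
        # centres c - 0.5 in [cuts[k], cuts[k+1]) -> columns
        c1 <- max(1L, as.integer(ceiling(cuts[k] + 0.5)))
        c2 <- min(W, as.integer(ceiling(cuts[k + 1] + 0.5)) - 1L)
        if (c1 <= c2) mask[r, c1:c2] <- value
      }
    }
  }
  mask
}

#' Convert a Labelme annotation document to a class mask
#'
#' Polygons are rasterised in file order, later polygons overwriting earlier
#' ones; unlabelled pixels are background (0).  A pixel belongs to a polygon
#' when its centre lies inside (even-odd rule).  Polygons with fewer than
#' three vertices are skipped with a warning; a label missing from
#' `classMap` is an error.
#'
#' @param annotation path to a Labelme JSON file, or the parsed document
#'   (a list with `shapes` and optionally `imageHeight`/`imageWidth`).
#' @param classMap named integer vector mapping labels to class indices.
#' @param size optional integer (H, W); required when the document lacks
#'   `imageHeight`/`imageWidth`.
#' @return integer `H x W` mask matrix.
#' @export
labelmeToMask <- function(annotation,
                          classMap = c(background = 0L, cow = 1L, beef = 2L),
                          size = NULL) {
  doc <- if (is.character(annotation))
    jsonlite::fromJSON(annotation, simplifyVector = FALSE) else annotation
  H <- doc$imageHeight %||% size[1]
  W <- doc$imageWidth %||% size[2]
  if (is.null(H) || is.null(W))
    stop("annotation lacks imageHeight/imageWidth; pass size = c(H, W)")
  mask <- matrix(0L, as.integer(H), as.integer(W))
  for (shape in doc$shapes %||% list()) {
    lab <- shape$label
    if (!lab %in% names(classMap))
      stop(sprintf("unknown annotation label '%s'; classMap defines: %s",
                   lab, paste(names(classMap), collapse = ", ")))
    pts <- shape$points
    xs <- vapply(pts, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(pts, function(p) as.numeric(p[[2]]), numeric(1))
    keep <- !duplicated(cbind(xs, ys))
    if (sum(keep) < 3) {
      warning(sprintf("skipping degenerate polygon for label '%s' (%d distinct vertices)",
                      lab, sum(keep)))
      next
    }
    mask <- fillPolygon(mask, xs, ys, as.integer(classMap[[lab]]))
  }
  mask
}

#' Read and write class masks as colour-coded PNG
#'
#' Masks are stored as RGB PNGs whose pixels carry the exact palette colour
#' of their class ([classPalette()]: background black, cow red, beef green).
#' 8-bit PNG represents these colours losslessly, so
#' `readMaskPNG(writeMaskPNG(mask))` is the identity.
#'
#' @param mask integer `H x W` label matrix.
#' @param path file path.
#' @param numClasses number of classes encoded in the palette.
#' @return `readMaskPNG` returns the integer label matrix.
#' @export
writeMaskPNG <- function(mask, path, numClasses = 3L) {
  pal <- classPalette(numClasses)
  if (max(mask) >= numClasses) stop("mask labels exceed the palette")
  img <- array(0, c(nrow(mask), ncol(mask), 3L))
  for (chn in 1:3) img[, , chn] <- pal[mask + 1L, chn]
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path, numClasses = 3L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  pal <- classPalette(numClasses)
  H <- dim(img)[1]; W <- dim(img)[2]
  code <- round(img[, , 1] * 255) * 66049 + round(img[, , 2] * 255) * 257 +
    round(img[, , 3] * 255)
  palCode <- round(pal[, 1] * 255) * 66049 + round(pal[, 2] * 255) * 257 +
    round(pal[, 3] * 255)
  idx <- match(as.vector(code), palCode)
  if (anyNA(idx))
    stop(sprintf("mask PNG '%s' contains %d pixel(s) with colours outside the class palette",
                 path, sum(is.na(idx))))
  matrix(as.integer(idx - 1L), H, W)
}

#' Read an RGB image file
#'
#' PNG files are read natively; JPEG files are read through EBImage when
#' that package is installed.
#'
#' @param path image file.
#' @return numeric `H x W x 3` array in `[0, 1]`.
#' @export
readImageRGB <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    stop("only PNG images are supported without EBImage: ", path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a scene to image + mask files
#'
#' @param scene a [LabeledScene-class].
#' @param imagePath,maskPath output PNG paths.
#' @param numClasses palette size for the mask encoding.
#' @return invisibly, the two paths.
#' @export
writeScenePNG <- function(scene, imagePath, maskPath, numClasses = 3L) {
  png::writePNG(scene@image, imagePath)
  writeMaskPNG(scene@mask, maskPath, numClasses)
  invisible(c(imagePath, maskPath))
}

#' Deterministic train/test split
#'
#' Shuffles scene indices under the seed and assigns the first
#' `round(ratio * N)` to the training set (round-half-even, R's `round`).
#' The two parts are disjoint and exhaustive.
#'
#' @param scenes list of scenes (or any list).
#' @param ratio training fraction in (0, 1); 0.8 gives the 8:2 split.
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
splitDataset <- function(scenes, ratio = 0.8, seed = 1L) {
  N <- length(scenes)
  if (N < 2L) stop("need at least 2 scenes to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  perm <- withSeed(seed, sample.int(N))
  nTrain <- round(ratio * N)
  nTrain <- max(1L, min(N - 1L, as.integer(nTrain)))
  list(train = scenes[perm[seq_len(nTrain)]],
       test = scenes[perm[(nTrain + 1L):N]])
}

#' Write a dataset manifest
#'
#' One row per scene: scene id, file path (if written), split membership,
#' fog flag and fog strength.
#'
#' @param sets named list of scene lists (e.g. `list(train = ..., test = ...)`).
#' @param path CSV output path.
#' @param paths optional named list of per-set character vectors of file
#'   paths.
#' @return the manifest data.frame, invisibly.
#' @export
writeManifest <- function(sets, path, paths = NULL) {
  rows <- do.call(rbind, lapply(names(sets), function(nm) {
    ss <- sets[[nm]]
    data.frame(
      scene_id = vapply(ss, function(s) s@sceneId, ""),
      path = if (!is.null(paths[[nm]])) paths[[nm]] else NA_character_,
      split = nm,
      fogged = vapply(ss, function(s) s@fogged, TRUE),
      beta = vapply(ss, function(s) s@fogStrength, 1.0))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
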