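#' Pixel confusion matrix
#'
#' An `NC x NC` table of pixel counts with rows indexed by ground-truth class
#' and columns by predicted class.  All five evaluation statistics (PA, CPA,
#' MPA, IoU, MIoU) derive from it.  Accumulation over batches is additive and
#' order-independent.
#'
#' @slot counts numeric NC x NC matrix of non-negative pixel counts (numeric
#'   storage so totals beyond the integer range are safe).
#' @slot classNames character vector of NC labels.
#' @export
setClass("ConfusionMatrix", representation(
  counts = "matrix", classNames = "character"),
  validity = function(object) {
    msg <- character(0)
    nc <- length(object@classNames)
    if (!all(dim(object@counts) == c(nc, nc)))
      msg <- c(msg, "counts must be NC x NC")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @param classNames class labels; the default is the three-class cattle
#'   problem (background, cow, beef).
#' @rdname ConfusionMatrix-class
#' @export
confusionMatrix <- function(classNames = c("background", "cow", "beef")) {
  nc <- length(classNames)
  new("ConfusionMatrix",
      counts = matrix(0, nc, nc, dimnames = list(truth = classNames,
                                                 predicted = classNames)),
      classNames = classNames)
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (%d classes, %s pixels)\n",
              length(object@classNames),
              format(sum(object@counts), big.mark = ",")))
  print(object@counts)
})

#' Accumulate pixel counts into a confusion matrix
#'
#' Each pixel with ground truth `g` and prediction `p` increments
#' `counts[g, p]` once.  Masks must have identical shape and labels in
#' `[0, NC)`; pixels whose truth equals `ignoreIndex` are skipped.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param predicted,truth integer label matrices/arrays (0-based labels).
#' @param ignoreIndex optional label to exclude from scoring (default none).
#' @return the updated [ConfusionMatrix-class].
#' @export
cmAccumulate <- function(cm, predicted, truth, ignoreIndex = NULL) {
  if (!identical(dim(predicted) %||% length(predicted),
                 dim(truth) %||% length(truth)))
    stop("predicted mask and truth mask have different shapes")
  nc <- length(cm@classNames)
  p <- as.integer(predicted)
  g <- as.integer(truth)
  if (!is.null(ignoreIndex)) {
    keep <- g != ignoreIndex
    p <- p[keep]; g <- g[keep]
  }
  if (length(p)) {
    if (min(p) < 0L || max(p) >= nc)
      stop(sprintf("predicted mask contains labels outside [0, %d)", nc))
    if (min(g) < 0L || max(g) >= nc)
      stop(sprintf("truth mask contains labels outside [0, %d)", nc))
    tab <- tabulate(g * nc + p + 1L, nbins = nc * nc)
    cm@counts <- cm@counts + matrix(tab, nc, nc, byrow = TRUE,
                                    dimnames = dimnames(cm@counts))
  }
  cm
}

#' Segmentation evaluation statistics
#'
#' @description
#' `pixelAccuracy`: fraction of correctly predicted pixels,
#' `trace(counts) / sum(counts)` — the multi-class form of
#' `(TP + TN) / (TP + FP + FN + TN)`.
#'
#' `classPixelAccuracy`: per-class pixel accuracy.  The printed formula is
#' `TP / (TP + FP)` (the predicted-positive denominator, i.e. precision),
#' implemented literally as the default; `mode = "recall"` switches the
#' denominator to the ground-truth count `TP / (TP + FN)` for users who read
#' "class pixel accuracy" in the recall sense.
#'
#' `meanPixelAccuracy`: arithmetic mean of the defined per-class accuracies.
#'
#' `classIoU`: `TP / (TP + FP + FN)`, intersection over union for one class.
#'
#' `meanIoU`: mean of the defined per-class IoU values.
#'
#' A class whose denominator is zero (absent from both masks) yields `NA`
#' and is excluded from the means; the exclusion is recorded in the
#' [MetricsReport-class].
#'
#' @param cm a [ConfusionMatrix-class].
#' @param class 0-based class label, as stored in masks.
#' @param mode `"precision"` (the printed formula) or `"recall"`.
#' @return a fraction in `[0, 1]`, or `NA` where undefined.
#' @export
pixelAccuracy <- function(cm) {
  tot <- sum(cm@counts)
  if (tot == 0) stop("pixel accuracy undefined: empty confusion matrix")
  sum(diag(cm@counts)) / tot
}

#' @rdname pixelAccuracy
#' @export
classPixelAccuracy <- function(cm, class, mode = c("precision", "recall")) {
  mode <- match.arg(mode)
  i <- as.integer(class) + 1L
  if (i < 1L || i > nrow(cm@counts)) stop("class index out of range")
  den <- if (mode == "precision") sum(cm@counts[, i]) else sum(cm@counts[i, ])
  if (den == 0) return(NA_real_)
  cm@counts[i, i] / den
}

#' @rdname pixelAccuracy
#' @export
meanPixelAccuracy <- function(cm, mode = c("precision", "recall")) {
  mode <- match.arg(mode)
  nc <- length(cm@classNames)
  cpa <- vapply(seq_len(nc) - 1L, classPixelAccuracy, numeric(1),
                cm = cm, mode = mode)
  if (all(is.na(cpa))) stop("mean pixel accuracy undefined: all classes empty")
  mean(cpa, na.rm = TRUE)
}

#' @rdname pixelAccuracy
#' @export
classIoU <- function(cm, class) {
  i <- as.integer(class) + 1L
  if (i < 1L || i > nrow(cm@counts)) stop("class index out of range")
  union <- sum(cm@counts[i, ]) + sum(cm@counts[, i]) - cm@counts[i, i]
  if (union == 0) return(NA_real_)
  cm@counts[i, i] / union
}

#' @rdname pixelAccuracy
#' @export
meanIoU <- function(cm) {
  nc <- length(cm@classNames)
  iou <- vapply(seq_len(nc) - 1L, classIoU, numeric(1), cm = cm)
  if (all(is.na(iou))) stop("mean IoU undefined: all classes empty")
  mean(iou, na.rm = TRUE)
}

#' Metrics report for one evaluation run
#'
#' @slot pa,mpa,miou overall fractions in `[0, 1]`.
#' @slot cpa,iou per-class fractions (named by class), `NA` where undefined.
#' @slot classNames class labels.
#' @slot excluded character vector naming classes excluded from the means
#'   because their denominators were zero.
#' @slot cm the underlying [ConfusionMatrix-class].
#' @export
setClass("MetricsReport", representation(
  pa = "numeric", mpa = "numeric", miou = "numeric",
  cpa = "numeric", iou = "numeric", classNames = "character",
  excluded = "character", cm = "ConfusionMatrix"))

#' Build a metrics report from a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class] with at least one scored pixel.
#' @param cpaMode `"precision"` (the default, the printed per-class formula)
#'   or `"recall"`.
#' @return a [MetricsReport-class].
#' @export
metricsReport <- function(cm, cpaMode = c("precision", "recall")) {
  cpaMode <- match.arg(cpaMode)
  nc <- length(cm@classNames)
  cpa <- vapply(seq_len(nc) - 1L, classPixelAccuracy, numeric(1),
                cm = cm, mode = cpaMode)
  iou <- vapply(seq_len(nc) - 1L, classIoU, numeric(1), cm = cm)
  names(cpa) <- names(iou) <- cm@classNames
  new("MetricsReport",
      pa = pixelAccuracy(cm),
      mpa = mean(cpa, na.rm = TRUE),
      miou = mean(iou, na.rm = TRUE),
      cpa = cpa, iou = iou, classNames = cm@classNames,
      excluded = cm@classNames[is.na(cpa) | is.na(iou)],
      cm = cm)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: PA %.4f  MPA %.4f  MIoU %.4f\n",
              object@pa, object@mpa, object@miou))
  for (i in seq_along(object@classNames))
    cat(sprintf("  %-12s CPA %.4f  IoU %.4f\n", object@classNames[i],
                object@cpa[i], object@iou[i]))
  if (length(object@excluded))
    cat("  excluded from means (zero denominator):",
        paste(object@excluded, collapse = ", "), "\n")
})

capitalize1 <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

#' Flatten a metrics report to a one-row table
#'
#' Columns follow the conventional layout of segmentation result tables:
#' `PA`, `MPA`, `MIoU`, then `CPA(<Class>)` and `IoU(<Class>)` for every
#' non-background class.
#'
#' @param report a [MetricsReport-class].
#' @param percent logical; report percentages instead of fractions.
#' @return a one-row data.frame.
#' @export
metricsRow <- function(report, percent = FALSE) {
  f <- if (percent) 100 else 1
  row <- data.frame(PA = report@pa * f, MPA = report@mpa * f,
                    MIoU = report@miou * f, check.names = FALSE)
  fg <- which(report@classNames != "background")
  for (i in fg)
    row[[sprintf("CPA(%s)", capitalize1(report@classNames[i]))]] <- report@cpa[i] * f
  for (i in fg)
    row[[sprintf("IoU(%s)", capitalize1(report@classNames[i]))]] <- report@iou[i] * f
  row
}

#' Write metrics to CSV or JSON
#'
#' @param reports a [MetricsReport-class] or named list of them (one row per
#'   name).
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @param percent report percentages instead of fractions.
#' @return the path, invisibly.
#' @export
writeMetrics <- function(reports, path, percent = FALSE) {
  if (is(reports, "MetricsReport")) reports <- list(result = reports)
  tab <- do.call(rbind, lapply(reports, metricsRow, percent = percent))
  tab <- cbind(data.frame(Model = names(reports)), tab)
  rownames(tab) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
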