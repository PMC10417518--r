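workedExampleCM <- function() {
  cm <- confusionMatrix()
  cm@counts[] <- matrix(c(4, 1, 0,
                          0, 3, 1,
                          1, 0, 2), 3, 3, byrow = TRUE)
  cm
}

test_that("accumulation counts pixels by (truth, prediction) pair", {
  cm <- confusionMatrix()
  cm <- cmAccumulate(cm, matrix(1L, 10, 10), matrix(1L, 10, 10))
  expect_equal(unname(cm@counts[2, 2]), 100)
  expect_equal(sum(cm@counts) - cm@counts[2, 2], 0)
  # empty masks leave the matrix unchanged
  cm2 <- cmAccumulate(cm, integer(0), integer(0))
  expect_equal(cm2@counts, cm@counts)
  # hand-counted triple
  cm3 <- cmAccumulate(confusionMatrix(), c(0L, 2L, 2L), c(0L, 1L, 2L))
  expect_equal(unname(cm3@counts["background", "background"]), 1)
  expect_equal(unname(cm3@counts["cow", "beef"]), 1)
  expect_equal(unname(cm3@counts["beef", "beef"]), 1)
  expect_equal(sum(cm3@counts), 3)
})

test_that("shape and label-range violations are reported against the offending mask", {
  cm <- confusionMatrix()
  expect_error(cmAccumulate(cm, matrix(0L, 2, 2), matrix(0L, 3, 2)), "shapes")
  expect_error(cmAccumulate(cm, matrix(5L, 2, 2), matrix(0L, 2, 2)),
               "predicted mask")
  expect_error(cmAccumulate(cm, matrix(0L, 2, 2), matrix(-1L, 2, 2)),
               "truth mask")
})

test_that("the worked three-class example reproduces the hand counts", {
  cm <- workedExampleCM()
  expect_equal(pixelAccuracy(cm), 0.75)
  expect_equal(classPixelAccuracy(cm, 0), 0.8)
  expect_equal(classPixelAccuracy(cm, 1), 0.75)
  expect_equal(classPixelAccuracy(cm, 2), 2 / 3)
  expect_equal(meanPixelAccuracy(cm), (0.8 + 0.75 + 2 / 3) / 3)
  expect_equal(classIoU(cm, 0), 4 / 6)
  expect_equal(classIoU(cm, 1), 3 / 5)
  expect_equal(classIoU(cm, 2), 2 / 4)
  expect_equal(meanIoU(cm), mean(c(4 / 6, 3 / 5, 1 / 2)))
  # recall mode divides by the ground-truth row instead
  expect_equal(classPixelAccuracy(cm, 0, mode = "recall"), 4 / 5)
  expect_equal(classPixelAccuracy(cm, 2, mode = "recall"), 2 / 3)
})

test_that("degenerate matrices raise or flag: empty, perfect, all-wrong", {
  expect_error(pixelAccuracy(confusionMatrix()), "empty")
  perfect <- cmAccumulate(confusionMatrix(), matrix(0:2, 3, 4),
                          matrix(0:2, 3, 4))
  expect_equal(pixelAccuracy(perfect), 1)
  expect_equal(meanIoU(perfect), 1)
  allWrong <- cmAccumulate(confusionMatrix(), matrix(1L, 4, 4), matrix(2L, 4, 4))
  expect_equal(pixelAccuracy(allWrong), 0)
  expect_equal(classIoU(allWrong, 1), 0)       # disjoint -> IoU 0
  expect_true(is.na(classIoU(allWrong, 0)))    # absent everywhere -> flagged
  rep <- metricsReport(allWrong)
  # background is absent from both masks; beef is never predicted, so its
  # precision-style CPA is also undefined -> both are annotated as excluded
  expect_setequal(rep@excluded, c("background", "beef"))
  expect_equal(unname(rep@iou[["beef"]]), 0)
})

test_that("every metric equals the brute-force counting oracle on random masks", {
  for (i in 1:8) {
    nc <- withr::with_seed(100 + i, sample(2:4, 1))
    H <- withr::with_seed(200 + i, sample(3:32, 1))
    W <- withr::with_seed(300 + i, sample(3:32, 1))
    truth <- randomMask(H, W, nc, seed = 400 + i)
    pred <- randomMask(H, W, nc, seed = 500 + i)
    cm <- cmAccumulate(confusionMatrix(paste0("c", seq_len(nc))), pred, truth)
    o <- oracleMetrics(pred, truth, nc)
    expect_equal(pixelAccuracy(cm), o$pa)
    for (cl in 0:(nc - 1)) {
      expect_equal(classPixelAccuracy(cm, cl), o$cpa[cl + 1])
      expect_equal(classIoU(cm, cl), o$iou[cl + 1])
    }
    expect_equal(meanPixelAccuracy(cm), o$mpa)
    expect_equal(meanIoU(cm), o$miou)
  }
})

test_that("relabelling both masks with one permutation leaves PA, MPA and MIoU unchanged", {
  truth <- randomMask(20, 20, 3, seed = 1)
  pred <- randomMask(20, 20, 3, seed = 2)
  cm <- cmAccumulate(confusionMatrix(), pred, truth)
  for (i in 1:4) {
    perm <- withr::with_seed(i, sample(0:2))
    cmP <- cmAccumulate(confusionMatrix(), matrix(perm[pred + 1], 20),
                        matrix(perm[truth + 1], 20))
    expect_equal(pixelAccuracy(cmP), pixelAccuracy(cm))
    expect_equal(meanPixelAccuracy(cmP), meanPixelAccuracy(cm))
    expect_equal(meanIoU(cmP), meanIoU(cm))
  }
})

test_that("IoU never exceeds per-class accuracy, and accumulation is additive", {
  t1 <- randomMask(15, 15, 3, seed = 3); p1 <- randomMask(15, 15, 3, seed = 4)
  t2 <- randomMask(10, 25, 3, seed = 5); p2 <- randomMask(10, 25, 3, seed = 6)
  cm <- cmAccumulate(cmAccumulate(confusionMatrix(), p1, t1), p2, t2)
  for (cl in 0:2)
    expect_lte(classIoU(cm, cl), classPixelAccuracy(cm, cl))
  cmCat <- cmAccumulate(confusionMatrix(), c(p1, p2), c(t1, t2))
  expect_equal(cm@counts, cmCat@counts)
  cmRev <- cmAccumulate(cmAccumulate(confusionMatrix(), p2, t2), p1, t1)
  expect_equal(cm@counts, cmRev@counts)
})

test_that("reports flatten to the conventional table columns and serialise", {
  rep <- metricsReport(workedExampleCM())
  row <- metricsRow(rep, percent = TRUE)
  expect_equal(names(row), c("PA", "MPA", "MIoU", "CPA(Cow)", "CPA(Beef)",
                             "IoU(Cow)", "IoU(Beef)"))
  expect_equal(row$PA, 75)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  writeMetrics(list(model = rep), csv)
  writeMetrics(list(model = rep), js)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(back$MIoU, rep@miou)
  expect_equal(jsonlite::fromJSON(js)$MIoU, rep@miou)
})
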