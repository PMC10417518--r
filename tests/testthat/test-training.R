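test_that("the poly schedule decays from lr0 to zero and is monotone", {
  expect_equal(polyLR(0, 100), 0.01)
  expect_equal(polyLR(100, 100), 0)
  expect_equal(polyLR(50, 100, lr0 = 0.01, power = 1), 0.005)
  lrs <- polyLR(0:200, 200)
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs <= 0.01))
  expect_error(polyLR(1, 0), "maxIterations")
  expect_error(polyLR(-1, 10), "iteration")
  expect_error(polyLR(11, 10), "iteration")
})

test_that("training is deterministic given the seed and reduces the loss", {
  scenes <- generateScenes(sceneRecipe(canvasSize = c(64L, 64L), seed = 51), 8)
  cfg <- deskTrainConfig(inputSize = 64L, epochs = 3L, seed = 2L)
  run <- function() {
    m <- buildModel(impVariant(), tinyNetworkOptions(seed = 3))
    trainModel(m, scenes, cfg)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$trace, f2$trace)
  expect_equal(nrow(f1$trace), 3 * ceiling(8 / 4))
  expect_lt(mean(tail(f1$trace$loss, 2)), f1$trace$loss[1])
  expect_true(all(diff(f1$trace$lr) < 0))
  # identical weights after the two runs
  x <- randomImageBatch(64, 64, 1, seed = 9)
  expect_identical(segForward(f1$model, x), segForward(f2$model, x))
})

test_that("training rejects empty sets and out-of-range labels", {
  m <- buildModel(impVariant(), tinyNetworkOptions(seed = 4))
  expect_error(trainModel(m, list(), deskTrainConfig()), "empty")
  sc <- generateScene(sceneRecipe(seed = 52))
  sc@mask[1, 1] <- 7L
  expect_error(trainModel(m, list(sc), deskTrainConfig()), "numClasses")
})

test_that("an oracle stub scores perfectly and a constant stub flags absent classes", {
  scenes <- generateScenes(sceneRecipe(seed = 53), 4)
  truthById <- setNames(lapply(scenes, function(s) s@mask),
                        vapply(scenes, function(s) s@sceneId, ""))
  i <- 0
  oracle <- local({
    k <- 0
    function(img) { k <<- k + 1; scenes[[k]]@mask }
  })
  rep <- evaluateModel(oracle, scenes)
  expect_equal(rep@pa, 1)
  expect_equal(rep@mpa, 1)
  expect_equal(rep@miou, 1)
  constant <- function(img) matrix(0L, dim(img)[1], dim(img)[2])
  repC <- evaluateModel(constant, scenes)
  expect_true(is.na(repC@cpa[["cow"]]))
  expect_true("cow" %in% repC@excluded)
  expect_equal(unname(repC@iou[["cow"]]), 0)
  expect_error(evaluateModel(constant, list()), "empty")
})

test_that("evaluation equals metrics-module scoring of masks saved to disk", {
  scenes <- generateScenes(sceneRecipe(canvasSize = c(64L, 64L), seed = 54), 3)
  m <- buildModel(impVariant(), tinyNetworkOptions(seed = 5))
  rep <- evaluateModel(m, scenes)
  cm <- confusionMatrix()
  for (sc in scenes) {
    path <- tempfile(fileext = ".png")
    writeMaskPNG(predictMask(m, sc@image), path)
    cm <- cmAccumulate(cm, readMaskPNG(path), sc@mask)
  }
  expect_equal(cm@counts, rep@cm@counts)
  expect_equal(metricsReport(cm)@miou, rep@miou)
})

test_that("a colour-separable dataset is segmented almost perfectly within twenty epochs", {
  train <- lapply(1:16, function(i) colorCodedScene(96L, seed = 60 + i))
  held <- lapply(1:6, function(i) colorCodedScene(96L, seed = 90 + i))
  m <- buildModel(impVariant(), deskNetworkOptions(seed = 6))
  fit <- trainModel(m, train, deskTrainConfig(epochs = 20L, seed = 7L))
  rep <- evaluateModel(m, held)
  expect_gte(rep@miou, 0.95)
})

test_that("the ablation harness emits one row per variant and test set with the table columns", {
  scenes <- generateScenes(sceneRecipe(canvasSize = c(64L, 64L), seed = 55), 10)
  sp <- splitDataset(scenes, 0.8, seed = 1)
  tab <- runAblation(list(imp = impVariant()), sp$train,
                     list(clear = sp$test),
                     deskTrainConfig(inputSize = 64L, epochs = 1L, seed = 8L),
                     tinyNetworkOptions(seed = 9))
  expect_equal(nrow(tab), 1L)
  expect_equal(colnames(tab),
               c("Model", "TestSet", "PA", "MPA", "MIoU", "CPA(Cow)",
                 "CPA(Beef)", "IoU(Cow)", "IoU(Beef)"))
})
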