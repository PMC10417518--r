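test_that("scene generation is bit-identical for an identical recipe and seed", {
  rec <- sceneRecipe(seed = 31)
  a <- generateScene(rec)
  b <- generateScene(rec)
  expect_identical(a@image, b@image)
  expect_identical(a@mask, b@mask)
  # different seed differs
  rec2 <- rec; rec2@seed <- 32L
  expect_false(identical(generateScene(rec2)@image, a@image))
})

test_that("animal count and class requests are honoured in the mask", {
  empty <- generateScene(sceneRecipe(nAnimals = c(0L, 0L), seed = 1))
  expect_equal(sum(empty@mask), 0)
  three <- generateScene(sceneRecipe(canvasSize = c(128L, 128L),
                                     nAnimals = c(3L, 3L), classMix = 1,
                                     occluderRate = 0, seed = 5))
  comp <- cattleseg:::labelComponents(three@mask == 1L)
  expect_equal(max(comp), 3L)
  expect_true(all(three@mask %in% c(0L, 1L)))
  beefOnly <- generateScene(sceneRecipe(nAnimals = c(2L, 2L), classMix = 0,
                                        occluderRate = 0, seed = 6))
  expect_true(all(beefOnly@mask %in% c(0L, 2L)))
  expect_gt(sum(beefOnly@mask == 2L), 0)
})

test_that("cow and beef pixel totals balance over many scenes at an even class mix", {
  scenes <- generateScenes(sceneRecipe(seed = 77), 200)
  cow <- sum(vapply(scenes, function(s) sum(s@mask == 1L), numeric(1)))
  beef <- sum(vapply(scenes, function(s) sum(s@mask == 2L), numeric(1)))
  expect_gt(cow / beef, 0.8)
  expect_lt(cow / beef, 1.25)
})

test_that("railing occluders relabel covered animal pixels as background", {
  rec <- sceneRecipe(canvasSize = c(96L, 96L), nAnimals = c(2L, 2L),
                     occluderRate = 3, seed = 9)
  sc <- generateScene(rec)
  clear <- generateScene(sceneRecipe(canvasSize = c(96L, 96L),
                                     nAnimals = c(2L, 2L), occluderRate = 0,
                                     seed = 9))
  # same animals drawn; occluded version can only lose foreground pixels
  expect_lte(sum(sc@mask > 0), sum(clear@mask > 0))
})

test_that("fog is identity at strength 0 and converges to airlight as strength grows", {
  sc <- generateScene(sceneRecipe(seed = 21))
  f0 <- applyFog(sc, 0)
  expect_identical(f0@image, sc@image)
  expect_true(f0@fogged)
  A <- c(0.9, 0.92, 0.95)
  fInf <- applyFog(sc, 1e9, airlight = A)
  expect_lt(max(abs(sweep(fInf@image, 3, A))), 1e-12)
  # monotone approach to the airlight
  dev <- vapply(c(0.3, 0.8, 1.5, 3), function(b)
    mean(abs(sweep(applyFog(sc, b, airlight = A)@image, 3, A))), numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("fog never alters masks, ids or the fog bookkeeping fields", {
  sc <- generateScene(sceneRecipe(seed = 22))
  for (b in c(0, 0.5, 2, 10)) {
    f <- applyFog(sc, b)
    expect_identical(f@mask, sc@mask)
    expect_equal(f@fogStrength, b)
  }
  expect_error(applyFog(sc, -1), "strength")
})

test_that("the fog protocol fogs the requested fraction and exposes companion sets", {
  scenes <- generateScenes(sceneRecipe(seed = 23), 20)
  pr <- fogTestProtocol(scenes, 0.5, seed = 3)
  expect_equal(sum(vapply(pr$mixed, function(s) s@fogged, TRUE)), 10L)
  expect_equal(sum(vapply(pr$sunny, function(s) s@fogged, TRUE)), 0L)
  expect_equal(sum(vapply(pr$foggy, function(s) s@fogged, TRUE)), 20L)
  expect_identical(fogTestProtocol(scenes, 0, seed = 3)$mixed, scenes)
  pr1 <- fogTestProtocol(scenes, 1, seed = 3)
  expect_true(all(vapply(pr1$mixed, function(s) s@fogged, TRUE)))
  # deterministic under the seed
  pr2 <- fogTestProtocol(scenes, 0.5, seed = 3)
  expect_identical(pr$foggedIds, pr2$foggedIds)
  # augment mode keeps the originals and appends the fogged copies
  prA <- fogTestProtocol(scenes, 0.5, seed = 3, mode = "augment")
  expect_equal(length(prA$mixed), 30L)
})

test_that("polygon annotations rasterise by pixel centre with overwrite-in-order", {
  doc <- list(imageHeight = 20, imageWidth = 20, shapes = list(
    list(label = "cow", points = list(list(3, 4), list(9, 4),
                                      list(9, 10), list(3, 10)))))
  mk <- labelmeToMask(doc)
  expect_equal(sum(mk == 1L), 36)          # 6 x 6 axis-aligned square
  expect_equal(dim(mk), c(20L, 20L))
  # no shapes -> all background
  expect_equal(sum(labelmeToMask(list(imageHeight = 5, imageWidth = 5,
                                      shapes = list()))), 0)
  # later polygons overwrite earlier ones
  doc2 <- list(imageHeight = 10, imageWidth = 10, shapes = list(
    list(label = "cow", points = list(list(1, 1), list(6, 1),
                                      list(6, 6), list(1, 6))),
    list(label = "beef", points = list(list(4, 4), list(9, 4),
                                       list(9, 9), list(4, 9)))))
  mk2 <- labelmeToMask(doc2)
  expect_true(all(mk2[5:6, 5:6] == 2L))
  expect_true(all(mk2[2:4, 2:4] == 1L))
  # unknown label names the label; degenerate polygon warns and is skipped
  bad <- list(imageHeight = 5, imageWidth = 5, shapes = list(
    list(label = "horse", points = list(list(0, 0), list(3, 0), list(3, 3)))))
  expect_error(labelmeToMask(bad), "horse")
  degen <- list(imageHeight = 5, imageWidth = 5, shapes = list(
    list(label = "cow", points = list(list(1, 1), list(1, 1), list(1, 1)))))
  expect_warning(mk3 <- labelmeToMask(degen), "degenerate")
  expect_equal(sum(mk3), 0)
})

test_that("labelme files round-trip through JSON on disk", {
  doc <- list(imageHeight = 12L, imageWidth = 16L, shapes = list(
    list(label = "beef", shape_type = "polygon",
         points = list(list(2, 2), list(10, 2), list(10, 8), list(2, 8)))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  mk <- labelmeToMask(path)
  expect_equal(dim(mk), c(12L, 16L))
  expect_equal(sum(mk == 2L), 48)
})

test_that("masks round-trip exactly through colour-coded PNG", {
  sc <- generateScene(sceneRecipe(seed = 24))
  path <- tempfile(fileext = ".png")
  writeMaskPNG(sc@mask, path)
  expect_identical(readMaskPNG(path), sc@mask)
  # scene image + mask writer pair
  ip <- tempfile(fileext = ".png"); mp <- tempfile(fileext = ".png")
  writeScenePNG(sc, ip, mp)
  img <- readImageRGB(ip)
  expect_equal(dim(img), dim(sc@image))
  expect_lt(max(abs(img - sc@image)), 1 / 255)
  expect_identical(readMaskPNG(mp), sc@mask)
})

test_that("the train/test split is deterministic, disjoint, exhaustive and rounds as documented", {
  scenes <- as.list(1:10)
  sp <- splitDataset(scenes, 0.8, seed = 4)
  expect_equal(length(sp$train), 8L)
  expect_equal(length(sp$test), 2L)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), 1:10)
  sp2 <- splitDataset(scenes, 0.8, seed = 4)
  expect_identical(sp, sp2)
  expect_false(identical(sp, splitDataset(scenes, 0.8, seed = 5)))
  # round-half-even rule at N = 781, ratio 0.5
  sp781 <- splitDataset(as.list(seq_len(781)), 0.5, seed = 1)
  expect_equal(length(sp781$train), round(0.5 * 781))
  expect_error(splitDataset(as.list(1), 0.5, seed = 1), "at least 2")
  expect_error(splitDataset(scenes, 1.2, seed = 1), "ratio")
})

test_that("the manifest lists every scene with split, fog flag and strength", {
  scenes <- generateScenes(sceneRecipe(seed = 25), 6)
  sp <- splitDataset(scenes, 0.8, seed = 1)
  path <- tempfile(fileext = ".csv")
  mf <- writeManifest(list(train = sp$train, test = sp$test), path)
  expect_equal(nrow(mf), 6L)
  expect_setequal(unique(mf$split), c("train", "test"))
  expect_true(file.exists(path))
})
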