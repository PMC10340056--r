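test_that("a parameter-free class yields a constant base-colour image", {
  params <- list(name = "flat", baseColor = c(210, 150, 180),
                 blobDensity = 0, blobEcc = 0.5, textureFreq = 0,
                 noiseSd = 0)
  set.seed(1)
  img <- generateClassImage(params, size = 16)
  expect_equal(dim(img), c(16L, 16L, 3L))
  for (ch in 1:3) {
    expect_true(all(img[, , ch] == params$baseColor[ch]))
  }
  expect_equal(attr(img, "blobCount"), 0L)
})

test_that("image generation is deterministic per seed and integer-valued", {
  p <- defaultClassParams()[[1]]
  set.seed(42)
  a <- generateClassImage(p, size = 24)
  set.seed(42)
  b <- generateClassImage(p, size = 24)
  expect_identical(a, b)
  expect_true(all(a == round(a)))
  expect_true(min(a) >= 0 && max(a) <= 255)
})

test_that("blob counts follow the configured Poisson intensity", {
  p <- defaultClassParams()[[1]]
  size <- 16
  lambda <- p$blobDensity * size^2
  set.seed(500)
  counts <- vapply(1:200, function(i) {
    attr(generateClassImage(p, size = size), "blobCount")
  }, numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("generated datasets are balanced, named and reproducible", {
  spec <- syntheticSpec(imagesPerClass = 4, imageSize = 16,
                        difficulty = 0.2, seed = 3)
  ds <- generateDataset(spec)
  expect_equal(length(ds), 20)
  expect_equal(as.vector(table(imageLabels(ds))), rep(4L, 5))
  expect_equal(classNames(ds),
               c("Col-Ad", "Col-Be", "Lun-Ad", "Lun-Be", "Lun-SC"))
  ds2 <- generateDataset(spec)
  expect_identical(imageData(ds), imageData(ds2))
})

test_that("difficulty 0 data are separable by mean colour alone", {
  spec <- syntheticSpec(imagesPerClass = 16, imageSize = 16,
                        difficulty = 0, seed = 7)
  sp <- splitDataset(generateDataset(spec), 0.75, seed = 7)
  expect_gt(centroidAccuracy(sp$train, sp$test), 95)
})

test_that("difficulty monotonically degrades the centroid baseline", {
  accAt <- function(difficulty, seed) {
    spec <- syntheticSpec(imagesPerClass = 12, imageSize = 16,
                          difficulty = difficulty, seed = seed)
    sp <- splitDataset(generateDataset(spec), 0.75, seed = seed)
    centroidAccuracy(sp$train, sp$test)
  }
  easy <- mean(vapply(1:5, function(s) accAt(0.2, s), numeric(1)))
  hard <- mean(vapply(1:5, function(s) accAt(0.8, s), numeric(1)))
  expect_lte(hard, easy)
})

test_that("datasets round-trip through a class-per-folder directory", {
  spec <- syntheticSpec(imagesPerClass = 3, imageSize = 16,
                        difficulty = 0.2, seed = 9)
  ds <- generateDataset(spec)
  root <- tempfile("histods")
  writeDataset(ds, root, format = "png")
  expect_true(file.exists(file.path(root, "manifest.csv")))
  back <- readDataset(root)
  # PNG is lossless: identical label multisets and pixel-exact images
  expect_equal(sort(classNames(back)), sort(classNames(ds)))
  tab <- function(s) table(classNames(s)[imageLabels(s)])
  expect_equal(tab(back), tab(ds))
  byClass <- function(s) {
    split(imageData(s), classNames(s)[imageLabels(s)])
  }
  orig <- byClass(ds)
  got <- byClass(back)
  for (cls in names(orig)) {
    for (i in seq_along(orig[[cls]])) {
      expect_equal(got[[cls]][[i]], orig[[cls]][[i]],
                   ignore_attr = TRUE)
    }
  }
  unlink(root, recursive = TRUE)
})

test_that("unknown class folders are skipped with a warning", {
  spec <- syntheticSpec(imagesPerClass = 2, imageSize = 16, seed = 2)
  ds <- generateDataset(spec)
  root <- tempfile("histods")
  writeDataset(ds, root)
  dir.create(file.path(root, "stray"))
  expect_warning(back <- readDataset(root, classNames = classNames(ds)),
                 "stray")
  expect_equal(length(back), length(ds))
  expect_error(readDataset(tempfile("missing")), "not exist")
  empty <- tempfile("emptyroot")
  dir.create(empty)
  expect_error(readDataset(empty), "no class folders")
  unlink(c(root, empty), recursive = TRUE)
})

test_that("splits are stratified, disjoint, exhaustive and seeded", {
  spec <- syntheticSpec(imagesPerClass = 10, imageSize = 16, seed = 5)
  ds <- generateDataset(spec) # 50 images
  sp <- splitDataset(ds, 0.8, seed = 1)
  expect_equal(length(sp$train), 40)
  expect_equal(length(sp$test), 10)
  expect_equal(as.vector(table(imageLabels(sp$train))), rep(8L, 5))
  expect_equal(as.vector(table(imageLabels(sp$test))), rep(2L, 5))
  sp2 <- splitDataset(ds, 0.8, seed = 1)
  expect_identical(imageLabels(sp$train), imageLabels(sp2$train))
  expect_identical(imageData(sp$test), imageData(sp2$test))
  tiny <- labeledImageSet(imageData(ds)[1], 1L, classNames(ds))
  expect_error(splitDataset(tiny, 0.8), "fewer than 2")
  expect_error(splitDataset(ds, 1.2), "between 0 and 1")
})
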