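writeToyTree <- function(root, classes, nPerClass, size = 16L, seed = 1L) {
  set.seed(seed)
  for (cl in classes) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nPerClass)) {
      img <- array(runif(size * size * 3), c(size, size, 3))
      png::writePNG(img, file.path(root, cl, sprintf("%s_%02d.png", cl, i)))
    }
  }
}

test_that("stratified 80/20 split arithmetic and determinism", {
  root <- withr::local_tempdir()
  writeToyTree(root, paste0("em", 1:7), 10)
  ds <- loadImageDataset(root, testFraction = 0.2, seed = 11)
  expect_length(trainIndices(ds), 56)
  expect_length(testIndices(ds), 14)
  labs <- imageLabels(ds)
  for (c in 0:6)
    expect_equal(sum(labs[testIndices(ds)] == c), 2)
  ds2 <- loadImageDataset(root, testFraction = 0.2, seed = 11)
  expect_identical(ds@split, ds2@split)
  ds3 <- loadImageDataset(root, testFraction = 0.2, seed = 12)
  expect_false(identical(ds3@split, ds2@split))
  # train and test are disjoint and cover all records
  expect_length(intersect(trainIndices(ds), testIndices(ds)), 0)
  expect_equal(sort(c(trainIndices(ds), testIndices(ds))), seq_len(70))
})

test_that("folder names map to class indices in lexicographic order", {
  root <- withr::local_tempdir()
  writeToyTree(root, c("Exploring", "Affectionate"), 3)
  ds <- loadImageDataset(root, testFraction = 0.34, seed = 1)
  expect_identical(classNames(ds), c("Affectionate", "Exploring"))
  expect_equal(unique(imageLabels(ds)[grepl("Affectionate", ds@paths)]), 0L)
  expect_equal(unique(imageLabels(ds)[grepl("Exploring", ds@paths)]), 1L)
})

test_that("undecodable files are skipped with a warning, not fatally", {
  root <- withr::local_tempdir()
  writeToyTree(root, c("a", "b"), 3)
  writeLines("not an image", file.path(root, "a", "broken.png"))
  expect_warning(ds <- loadImageDataset(root, 0.34, seed = 1),
                 "undecodable")
  expect_equal(length(ds), 6)
})

test_that("degenerate augmentation reduces to the normalized resize", {
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  cfg <- augmentationConfig(cropSize = 16, cropScale = c(1, 1), pHflip = 0,
                            jitter = c(0, 0, 0, 0), pJitter = 0)
  v <- twoViewAugment(img, cfg, seed = 5)
  ref <- evalTransform(img, 16)
  expect_equal(v$viewA, ref, tolerance = 1e-12)
  expect_equal(v$viewB, ref, tolerance = 1e-12)
})

test_that("augmentation is deterministic under a fixed seed and has
           non-degenerate stochastic support", {
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  cfg <- augmentationConfig(cropSize = 16)
  p1 <- twoViewAugment(img, cfg, seed = 3)
  p2 <- twoViewAugment(img, cfg, seed = 3)
  expect_identical(p1, p2)

  set.seed(9)
  differs <- vapply(1:100, function(i) {
    p <- twoViewAugment(img, cfg)
    !isTRUE(all.equal(p$viewA, p$viewB))
  }, logical(1))
  expect_gt(sum(differs), 95)
})

test_that("views always have the configured crop shape", {
  cfg <- augmentationConfig(cropSize = 12)
  for (d in list(c(16, 16), c(9, 30), c(40, 8))) {
    img <- array(runif(prod(d) * 3), c(d, 3))
    p <- twoViewAugment(img, cfg, seed = 1)
    expect_equal(dim(p$viewA), c(12, 12, 3))
    expect_equal(dim(p$viewB), c(12, 12, 3))
  }
})

test_that("eval transform is deterministic, shape-stable and normalizes", {
  img <- array(runif(15 * 31 * 3), c(15, 31, 3))
  expect_identical(evalTransform(img, 16), evalTransform(img, 16))
  expect_equal(dim(evalTransform(img, 16)), c(16, 16, 3))
  const <- array(0.3, c(10, 10, 3))
  out <- evalTransform(const, 8, mean = c(0.3, 0.3, 0.3), std = c(1, 1, 1))
  expect_equal(max(abs(out)), 0, tolerance = 1e-12)
})
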