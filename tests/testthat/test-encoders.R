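# Independent parameter-count oracle: explicit layer-by-layer arithmetic for
# the small-image (CIFAR-recipe) basic-block residual nets.
handCountParams <- function(widths, blocks, stem, featureDim) {
  conv <- function(k, cin, cout) k * k * cin * cout
  bn <- function(c) 2 * c
  total <- conv(3, 3, stem) + bn(stem)
  inC <- stem
  for (s in seq_along(widths)) {
    w <- widths[s]
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1 && s > 1) 2 else 1
      total <- total + conv(3, inC, w) + bn(w) + conv(3, w, w) + bn(w)
      if (stride != 1 || inC != w) total <- total + conv(1, inC, w) + bn(w)
      inC <- w
    }
  }
  total + inC * featureDim + featureDim # final linear with bias
}

test_that("modified resnet18 emits 128-length unit-norm features at 96 px", {
  enc <- sharedRun("enc18", buildEncoder(encoderConfig("resnet18"), seed = 1))
  x <- array(runif(96 * 96 * 3 * 2), c(96, 96, 3, 2))
  f <- encoderForward(enc, x)$features
  expect_equal(dim(f), c(2, 128))
  expect_equal(sqrt(rowSums(f^2)), c(1, 1), tolerance = 1e-5)
})

test_that("the small-image recipe has a 3x3 stride-1 stem and no stem pool", {
  enc <- sharedRun("enc18", buildEncoder(encoderConfig("resnet18"), seed = 1))
  si <- encoderStemInfo(enc)
  expect_equal(si$kernel, 3)
  expect_equal(si$stride, 1)
  expect_false(si$hasStemPool)
  enc34 <- buildEncoder(encoderConfig("resnet34", featureDim = 128),
                        seed = 1)
  si34 <- encoderStemInfo(enc34)
  expect_equal(si34$kernel, 3)
  expect_equal(si34$stride, 1)
  expect_false(si34$hasStemPool)
  expect_equal(enc34@config$featureDim, 128)
})

test_that("parameter counts match the hand-summed oracle", {
  enc <- sharedRun("enc18", buildEncoder(encoderConfig("resnet18"), seed = 1))
  expect_equal(nParameters(enc),
               handCountParams(c(64, 128, 256, 512), c(2, 2, 2, 2), 64, 128))
  enc8 <- buildEncoder(encoderConfig("resnet8", featureDim = 32,
                                     numBnSplits = 2), seed = 1)
  expect_equal(nParameters(enc8),
               handCountParams(c(16, 32, 64), c(1, 1, 1), 16, 32))
})

test_that("eval-mode forward is deterministic and batch-size independent", {
  enc <- buildEncoder(encoderConfig("resnet8", featureDim = 16,
                                    numBnSplits = 2), seed = 2)
  set.seed(4)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  fAll <- encoderForward(enc, x)$features
  fAll2 <- encoderForward(enc, x)$features
  expect_identical(fAll, fAll2)
  for (i in 1:4) {
    fi <- encoderForward(enc, x[, , , i, drop = FALSE])$features
    expect_equal(as.vector(fi), fAll[i, ], tolerance = 1e-10)
  }
})

test_that("imagenet-recipe and simclr stems are built as configured", {
  enc50 <- buildEncoder(encoderConfig("resnet50", featureDim = 8,
                                      numBnSplits = 1), seed = 1)
  si <- encoderStemInfo(enc50)
  expect_equal(si$kernel, 7)
  expect_equal(si$stride, 2)
  expect_true(si$hasStemPool)

  encS <- buildEncoder(encoderConfig("resnet8", featureDim = 8,
                                     numBnSplits = 1, simclrStem = TRUE),
                       seed = 1)
  siS <- encoderStemInfo(encS)
  expect_equal(siS$kernel, 3)
  expect_equal(siS$stride, 1)
  expect_equal(siS$pad, 0)
  expect_true(siS$hasStemPool)
})

test_that("pretrained weights are refused with an informative error", {
  expect_error(buildEncoder(encoderConfig("resnet8", pretrained = TRUE)),
               "pretrained")
})

test_that("projection head maps 2048 to 128 through a 2048-wide ReLU MLP", {
  head <- buildProjectionHead(seed = 1)
  x <- matrix(runif(5 * 2048), 5, 2048)
  out <- forwardModule(head, x)
  expect_equal(dim(out), c(5, 128))

  zero <- nnSetParams(head, lapply(nnParams(head), function(p) p * 0))
  expect_equal(max(abs(forwardModule(zero, x))), 0)
})

test_that("projection head forward equals the hand matrix product", {
  head <- buildProjectionHead(4, 4, 3, seed = 1)
  W2 <- matrix(seq(-0.4, 0.7, length.out = 12), 3, 4)
  params <- nnParams(head)
  params[["1/w"]] <- diag(4)
  params[["1/b"]] <- rep(0, 4)
  params[["3/w"]] <- W2
  params[["3/b"]] <- c(0.1, -0.2, 0.3)
  head <- nnSetParams(head, params)
  x <- matrix(c(0.5, 1, 2, 0.25), 1, 4) # non-negative: ReLU is identity
  expect_equal(forwardModule(head, x),
               x %*% t(W2) + rep(c(0.1, -0.2, 0.3), each = 1),
               tolerance = 1e-12)
})

test_that("encoder outputs stay unit-norm across random inputs", {
  enc <- buildEncoder(encoderConfig("resnet8", featureDim = 24,
                                    numBnSplits = 2), seed = 3)
  set.seed(10)
  for (i in 1:3) {
    x <- array(rnorm(16 * 16 * 3 * 4), c(16, 16, 3, 4))
    f <- encoderForward(enc, x, training = (i == 1))$features
    expect_equal(sqrt(rowSums(f^2)), rep(1, 4), tolerance = 1e-5)
  }
})
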