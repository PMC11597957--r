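test_that("self-retrieval with k = 1 returns the query's own label", {
  set.seed(1)
  f <- randUnitRows(6, 4)
  bank <- memoryBank(f, c(0L, 1L, 2L, 0L, 1L, 2L), 3)
  cfg <- knnConfig(k = 1, temperature = 0.1, numClasses = 3)
  pred <- knnPredict(f, bank, cfg)
  expect_equal(pred$labels, c(0L, 1L, 2L, 0L, 1L, 2L))
  expect_equal(pred$scores[cbind(1:6, pred$labels + 1)], rep(1, 6))
})

test_that("temperature weighting follows the hand-computed example", {
  bank <- memoryBank(rbind(c(1, 0), c(0.9, sqrt(0.19)), c(0, 1), c(-1, 0)),
                     c(0L, 0L, 1L, 1L), 2)
  cfg <- knnConfig(k = 3, temperature = 0.1, numClasses = 2)
  pred <- knnPredict(matrix(c(1, 0), 1), bank, cfg)
  expect_equal(pred$labels, 0L)
  # weights e^10, e^9 for class A vs e^0 for class B
  wA <- exp(10) + exp(9)
  wB <- exp(0)
  expect_equal(pred$scores[1, ], c(wA, wB) / (wA + wB), tolerance = 1e-10)
})

test_that("a single-class bank predicts that class regardless of k and
           temperature", {
  set.seed(2)
  bank <- memoryBank(randUnitRows(10, 3), rep(2L, 10), 4)
  q <- randUnitRows(5, 3)
  for (k in c(1, 3, 10)) for (tmp in c(0.05, 1)) {
    pred <- knnPredict(q, bank, knnConfig(k, tmp, 4))
    expect_equal(pred$labels, rep(2L, 5))
  }
})

test_that("knnPredict agrees exactly with the brute-force oracle on random
           instances", {
  set.seed(33)
  for (i in 1:200) {
    N <- sample(2:50, 1)
    d <- sample(2:8, 1)
    k <- sample(1:N, 1)
    C <- sample(2:5, 1)
    temp <- runif(1, 0.05, 1)
    bankF <- randUnitRows(N, d)
    bankL <- as.integer(sample(0:(C - 1), N, replace = TRUE))
    # ensure every class is arbitrary; bank need not contain all classes
    q <- randUnitRows(3, d)
    pred <- knnPredict(q, memoryBank(bankF, bankL, C),
                       knnConfig(k, temp, C))
    oracle <- bruteForceKnn(q, bankF, bankL, k, temp, C)
    expect_identical(pred$labels, as.integer(oracle[, 1]))
    expect_equal(pred$scores, oracle[, -1, drop = FALSE],
                 tolerance = 1e-10)
  }
})

test_that("constant features resolve deterministically by index
           tie-breaking", {
  d <- 4
  f <- matrix(rep(c(1, 0, 0, 0), 6), 6, d, byrow = TRUE)
  labs <- c(1L, 0L, 1L, 0L, 0L, 1L)
  bank <- memoryBank(f, labs, 2)
  q <- matrix(c(1, 0, 0, 0), 1)
  # all similarities tie at 1; top-k must be the lowest bank indices
  pred3 <- knnPredict(q, bank, knnConfig(3, 0.1, 2))
  # neighbours 1,2,3 -> labels 1,0,1 -> class 1 wins
  expect_equal(pred3$labels, 1L)
  pred2 <- knnPredict(q, bank, knnConfig(2, 0.1, 2))
  # neighbours 1,2 -> labels 1,0 -> equal scores -> smallest class index
  expect_equal(pred2$labels, 0L)
})

test_that("permuting the bank leaves predictions unchanged away from ties", {
  set.seed(44)
  bankF <- randUnitRows(30, 5)
  bankL <- as.integer(sample(0:2, 30, replace = TRUE))
  q <- randUnitRows(8, 5)
  cfg <- knnConfig(7, 0.2, 3)
  p1 <- knnPredict(q, memoryBank(bankF, bankL, 3), cfg)
  perm <- sample(30)
  p2 <- knnPredict(q, memoryBank(bankF[perm, ], bankL[perm], 3), cfg)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
})

test_that("predictions are invariant to a common orthogonal rotation", {
  set.seed(55)
  d <- 6
  R <- qr.Q(qr(matrix(rnorm(d * d), d)))
  bankF <- randUnitRows(25, d)
  bankL <- as.integer(sample(0:3, 25, replace = TRUE))
  q <- randUnitRows(10, d)
  cfg <- knnConfig(5, 0.1, 4)
  p1 <- knnPredict(q, memoryBank(bankF, bankL, 4), cfg)
  p2 <- knnPredict(q %*% R, memoryBank(bankF %*% R, bankL, 4), cfg)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-8)
})

test_that("random features with shuffled labels sit at chance level", {
  set.seed(66)
  n <- 700
  bankF <- randUnitRows(n, 16)
  bankL <- as.integer(rep(0:6, each = 100))
  q <- randUnitRows(400, 16)
  pred <- knnPredict(q, memoryBank(bankF, sample(bankL), 7),
                     knnConfig(200, 0.1, 7))
  # truth is uniform-random too; compare against an arbitrary balanced truth
  truth <- as.integer(sample(rep(0:6, length.out = 400)))
  acc <- mean(pred$labels == truth)
  ci <- qbinom(c(0.005, 0.995), 400, 1 / 7) / 400
  expect_gte(acc, ci[1])
  expect_lte(acc, ci[2])
})

test_that("classification report matches the hand confusion-matrix oracle", {
  rep1 <- classificationReport(c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L),
                               c("A", "B"))
  expect_equal(rep1@perClass$precision[2], 2 / 3, tolerance = 1e-12)
  expect_equal(rep1@perClass$recall[1], 1 / 2, tolerance = 1e-12)
  expect_equal(rep1@accuracy, 75)
  expect_equal(rep1@perClass$f1[1], 2 * 1 * 0.5 / 1.5, tolerance = 1e-12)
  expect_equal(rep1@perClass$support, c(2L, 2L))
  expect_named(rep1@perClass, c("class", "precision", "recall", "f1",
                                "support"))

  perfect <- classificationReport(c(0L, 1L, 2L), c(0L, 1L, 2L),
                                  c("x", "y", "z"))
  expect_equal(perfect@accuracy, 100)
  expect_equal(perfect@perClass$precision, rep(1, 3))
  expect_equal(perfect@perClass$recall, rep(1, 3))
  expect_equal(perfect@perClass$f1, rep(1, 3))
  expect_equal(perfect@macroF1, 1)

  expect_error(classificationReport(c(0L, 1L), c(0L), c("A", "B")),
               "equal length")
  expect_error(classificationReport(integer(0), integer(0), c("A", "B")),
               "empty")
})
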