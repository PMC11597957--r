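test_that("contrastive loss matches hand-computed softmax values", {
  q <- matrix(c(1, 0), 1)
  expect_equal(contrastiveLoss(q, q, NULL, tau = 0.7), 0, tolerance = 1e-12)
  neg <- matrix(c(0, 1), 1)
  expect_equal(contrastiveLoss(q, q, neg, tau = 1), log(1 + exp(-1)),
               tolerance = 1e-6)
  expect_equal(contrastiveLoss(q, q, neg, tau = 0.1), log(1 + exp(-10)),
               tolerance = 1e-6)
})

test_that("contrastive loss equals an independent (1+K)-way cross-entropy
           oracle on random instances", {
  set.seed(42)
  for (i in 1:200) {
    K <- sample(0:32, 1)
    d <- sample(2:8, 1)
    B <- sample(1:4, 1)
    tau <- runif(1, 0.05, 2)
    q <- randUnitRows(B, d)
    k <- randUnitRows(B, d)
    queue <- if (K > 0) randUnitRows(K, d) else NULL
    oracle <- mean(vapply(seq_len(B), function(b) {
      logits <- c(sum(q[b, ] * k[b, ]),
                  if (K > 0) as.vector(queue %*% q[b, ])) / tau
      softmaxCE0(logits)
    }, numeric(1)))
    expect_equal(contrastiveLoss(q, k, queue, tau), oracle,
                 tolerance = 1e-6)
  }
})

test_that("contrastive loss gradient matches finite differences", {
  set.seed(5)
  q <- randUnitRows(3, 4)
  k <- randUnitRows(3, 4)
  queue <- randUnitRows(6, 4)
  g <- contrastiveLossGrad(q, k, queue, tau = 0.3)
  eps <- 1e-6
  for (i in sample(length(q), 5)) {
    qp <- q; qp[i] <- q[i] + eps
    qm <- q; qm[i] <- q[i] - eps
    num <- (contrastiveLoss(qp, k, queue, 0.3) -
              contrastiveLoss(qm, k, queue, 0.3)) / (2 * eps)
    expect_equal(g$dq[i], num, tolerance = 1e-5)
  }
})

test_that("loss is non-increasing as temperature decreases when the
           positive dominates the negatives", {
  q <- matrix(c(0.8, 0.6), 1)
  k <- matrix(c(0.8, 0.6), 1)
  queue <- rbind(c(0, 1), c(-1, 0), c(0.6, -0.8))
  taus <- c(1, 0.5, 0.2, 0.1, 0.05)
  losses <- vapply(taus, function(t) contrastiveLoss(q, k, queue, t),
                   numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("EMA update obeys the identity, copy and interpolation cases", {
  qp <- list(a = matrix(1:4, 2), b = c(0.5, -0.5))
  kp <- list(a = matrix(0, 2, 2), b = c(0, 0))
  expect_identical(emaUpdate(qp, kp, 1), kp)
  expect_equal(emaUpdate(qp, kp, 0), qp)
  expect_equal(emaUpdate(list(a = 1), list(a = 0), 0.99)$a, 0.01,
               tolerance = 1e-12)
  expect_error(emaUpdate(list(a = matrix(1, 2, 2)), list(a = matrix(1, 2, 3)),
                         0.5), "mismatch")
})

test_that("queue enqueue has FIFO ring-buffer semantics", {
  set.seed(6)
  enc <- buildEncoder(encoderConfig("resnet8", featureDim = 4,
                                    numBnSplits = 1), seed = 1)
  st <- mocoState(enc, queueSize = 4, momentum = 0.9, temperature = 0.1)
  old <- st@queue
  st@queuePtr <- 2L
  keys <- randUnitRows(2, 4)
  st2 <- enqueueDequeue(st, keys)
  expect_equal(st2@queue[3:4, ], keys)         # 0-based rows 2,3
  expect_equal(st2@queue[1:2, ], old[1:2, ])   # untouched rows
  expect_equal(st2@queuePtr, 0L)               # wrapped
  expect_equal(nrow(st2@queue), 4)
  expect_error(enqueueDequeue(st, randUnitRows(5, 4)), "exceeds")
})

test_that("enqueueing queueSize keys replaces every row exactly once", {
  set.seed(7)
  enc <- buildEncoder(encoderConfig("resnet8", featureDim = 4,
                                    numBnSplits = 1), seed = 1)
  K <- 12
  st <- mocoState(enc, queueSize = K, momentum = 0.9, temperature = 0.1)
  # simulation oracle: track the age of each row under FIFO semantics
  age <- rep(0L, K)
  step <- 0L
  for (b in c(5, 3, 4)) {
    keys <- randUnitRows(b, 4)
    rows <- ((st@queuePtr + seq_len(b) - 1L) %% K) + 1L
    st <- enqueueDequeue(st, keys)
    step <- step + 1L
    age[rows] <- step
    expect_equal(sqrt(rowSums(st@queue^2)), rep(1, K), tolerance = 1e-5)
  }
  expect_true(all(age > 0))          # every original row replaced
  expect_equal(tabulate(age, 3), c(5, 3, 4)) # each exactly once per batch
  expect_equal(st@queuePtr, 0L)
})

test_that("a short momentum-contrast run keeps its bookkeeping contracts", {
  ds <- tinyDataset(nClasses = 2, nPerClass = 10, size = 16, seed = 9,
                    testFraction = 0.2)
  encCfg <- encoderConfig("resnet8", featureDim = 16, numBnSplits = 2)
  cfg <- mocoTrainConfig(batchSize = 8, learningRate = 0.05, epochs = 2,
                         queueSize = 32, knnK = 5, imageResolution = 16,
                         seed = 21)
  res <- sharedRun("mocoTiny", trainMoCo(ds, encCfg, cfg))
  expect_equal(nrow(res$history), 2)
  expect_named(res$history, c("epoch", "train_loss", "knn_accuracy_pct"))
  expect_true(all(is.finite(res$history$train_loss)))
  expect_true(all(res$history$knn_accuracy_pct >= 0 &
                    res$history$knn_accuracy_pct <= 100))
  expect_equal(sqrt(rowSums(res$state@queue^2)),
               rep(1, 32), tolerance = 1e-5)
})

test_that("training is reproducible under a fixed seed", {
  ds <- tinyDataset(nClasses = 2, nPerClass = 10, size = 16, seed = 9,
                    testFraction = 0.2)
  encCfg <- encoderConfig("resnet8", featureDim = 16, numBnSplits = 2)
  cfg <- mocoTrainConfig(batchSize = 8, learningRate = 0.05, epochs = 2,
                         queueSize = 32, knnK = 5, imageResolution = 16,
                         seed = 21)
  res1 <- sharedRun("mocoTiny", trainMoCo(ds, encCfg, cfg))
  res2 <- trainMoCo(ds, encCfg, cfg)
  expect_equal(res1$history, res2$history, tolerance = 1e-12)
})

test_that("SGD steps reduce the contrastive loss on a fixed task", {
  # Optimization sanity decoupled from queue nonstationarity: frozen queue,
  # frozen keys, fixed batch; repeated steps must drive the loss down.
  ds <- tinyDataset(nClasses = 2, nPerClass = 8, size = 16, seed = 25,
                    testFraction = 0.25)
  enc <- buildEncoder(encoderConfig("resnet8", featureDim = 8,
                                    numBnSplits = 2), seed = 8)
  set.seed(31)
  queue <- randUnitRows(32, 8)
  idx <- trainIndices(ds)[1:8]
  aug <- augmentationConfig(cropSize = 16)
  tv <- withr::with_seed(77, makeTwoViewBatch(ds, idx, aug))
  kFeat <- encoderForward(enc, tv$viewB)$features
  optState <- NULL
  losses <- numeric(15)
  for (it in 1:15) {
    fq <- encoderForward(enc, tv$viewA, training = TRUE)
    enc <- fq$encoder
    lg <- contrastiveLossGrad(fq$features, kFeat, queue, 0.1)
    losses[it] <- lg$loss
    bk <- nnBackward(enc@net, fq$cache, lg$dq)
    st <- emoco:::sgdMomentumStep(nnParams(enc@net),
                                  nnFlattenGrads(enc@net, bk$grads),
                                  optState, lr = 0.05)
    optState <- st$state
    enc@net <- nnSetParams(enc@net, st$params)
  }
  expect_lt(losses[15], losses[1])
})

test_that("m = 1 freezes the key encoder for the whole run", {
  ds <- tinyDataset(nClasses = 2, nPerClass = 8, size = 16, seed = 13,
                    testFraction = 0.25)
  encCfg <- encoderConfig("resnet8", featureDim = 8, numBnSplits = 2)
  cfg <- mocoTrainConfig(batchSize = 4, learningRate = 0.05, epochs = 1,
                         queueSize = 16, knnK = 3, momentum = 1,
                         imageResolution = 16, seed = 2)
  res <- trainMoCo(ds, encCfg, cfg)
  # rebuild the initial encoder exactly as trainMoCo does
  set.seed(cfg$seed)
  init <- buildEncoder(encCfg)
  expect_identical(nnParams(res$state@keyEncoder@net), nnParams(init@net))
  # while the query encoder has moved
  expect_false(identical(nnParams(res$encoder@net), nnParams(init@net)))
})
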