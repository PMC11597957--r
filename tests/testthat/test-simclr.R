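test_that("in-batch NT-Xent matches hand-computed values", {
  # one pair, no negatives
  z1 <- rbind(c(1, 0), c(1, 0))
  expect_equal(ntxentInBatchLoss(z1, tau = 0.5), 0, tolerance = 1e-12)
  # two orthogonal pairs at tau = 1: per-anchor -ln(e / (e + 2))
  z2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(ntxentInBatchLoss(z2, tau = 1), log(1 + 2 * exp(-1)),
               tolerance = 1e-6)
  expect_error(ntxentInBatchLoss(z2[1:3, ], tau = 1), "even")
  expect_error(ntxentInBatchLoss(z2, tau = 0), "positive")
})

test_that("NT-Xent is invariant under a common orthogonal rotation and
           non-negative", {
  set.seed(8)
  z <- randUnitRows(12, 5)
  R <- qr.Q(qr(matrix(rnorm(25), 5)))
  expect_equal(ntxentInBatchLoss(z, 0.5), ntxentInBatchLoss(z %*% R, 0.5),
               tolerance = 1e-8)
  for (i in 1:5) {
    z <- randUnitRows(2 * sample(1:8, 1), 4)
    expect_gte(ntxentInBatchLoss(z, runif(1, 0.1, 1)), 0)
  }
})

test_that("NT-Xent on random high-dimensional vectors approaches
           log(2B - 1)", {
  set.seed(9)
  B <- 64
  z <- randUnitRows(2 * B, 128)
  expect_equal(ntxentInBatchLoss(z, 1), log(2 * B - 1), tolerance = 0.1)
})

test_that("NT-Xent gradient matches finite differences", {
  set.seed(10)
  z <- matrix(rnorm(8 * 3), 8, 3) # unnormalized; ntxentGrad normalizes
  g <- ntxentGrad(z, tau = 0.4)
  f <- function(z) ntxentGrad(z, 0.4, wantGrad = FALSE)$loss
  eps <- 1e-6
  for (i in sample(length(z), 6)) {
    zp <- z; zp[i] <- z[i] + eps
    zm <- z; zm[i] <- z[i] - eps
    expect_equal(g$dz[i], (f(zp) - f(zm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("warmup-cosine schedule hits the documented anchor points", {
  base <- 0.2; w <- 10; T_ <- 500
  expect_equal(warmupCosineLR(w, base, w, T_), base)          # junction
  expect_equal(warmupCosineLR(0, base, w, T_), base / w)      # ramp start
  mid <- w + (T_ - w) / 2
  expect_equal(warmupCosineLR(mid, base, w, T_), base / 2)    # cosine mid
  tail <- warmupCosineLR(T_ - 1, base, w, T_)
  expect_lt(tail, 1e-4)                                       # near zero
  expect_equal(tail, base * 0.5 * (1 + cos(pi * (T_ - 1 - w) / (T_ - w))))
  expect_error(warmupCosineLR(T_, base, w, T_))
  expect_error(warmupCosineLR(-1, base, w, T_))
})

test_that("LARS steps follow the update rule and its invariances", {
  # zero gradient, zero weight decay: unchanged
  p <- list(w = matrix(c(1, 2, 3, 4), 2))
  g <- list(w = matrix(0, 2, 2))
  st <- larsStep(p, g, lr = 0.1, weightDecay = 0)
  expect_equal(st$params$w, p$w)

  # hand evaluation: w = 1, g = 1, wd = 0, trust = 1, lr = 0.1 -> w' = 0.9
  st2 <- larsStep(list(w = matrix(1, 1, 1)), list(w = matrix(1, 1, 1)),
                  lr = 0.1, weightDecay = 0, trustCoefficient = 1)
  expect_equal(as.numeric(st2$params$w), 0.9, tolerance = 1e-12)

  # scaling weights and grads by c > 0 leaves the relative update unchanged
  set.seed(11)
  w <- matrix(rnorm(6), 2, 3)
  gr <- matrix(rnorm(6), 2, 3)
  s1 <- larsStep(list(w = w), list(w = gr), lr = 0.05, weightDecay = 0)
  s3 <- larsStep(list(w = 3 * w), list(w = 3 * gr), lr = 0.05,
                 weightDecay = 0)
  expect_equal(s3$params$w / 3, s1$params$w, tolerance = 1e-10)

  # 1-d parameters are excluded from adaptation by default
  sBias <- larsStep(list(b = c(1, 1)), list(b = c(1, 1)), lr = 0.1,
                    weightDecay = 0.5)
  expect_equal(sBias$params$b, c(0.9, 0.9)) # plain SGD step, no decay

  expect_error(larsStep(list(w = matrix(1)), list(w = matrix(NaN)),
                        lr = 0.1), "non-finite")
})

test_that("t-SNE embeds with the expected shape, determinism and
           precondition", {
  set.seed(12)
  f <- matrix(rnorm(200 * 8), 200, 8)
  y1 <- tsneEmbed(f, perplexity = 50, seed = 4, nIter = 60)
  expect_equal(dim(y1), c(200, 2))
  expect_true(all(is.finite(y1)))
  y2 <- tsneEmbed(f, perplexity = 50, seed = 4, nIter = 60)
  expect_identical(y1, y2)
  expect_error(tsneEmbed(matrix(rnorm(20), 10, 2), perplexity = 50),
               "perplexity")
})

test_that("t-SNE separates well-separated clusters", {
  set.seed(13)
  f <- rbind(matrix(rnorm(60 * 4, mean = 0), ncol = 4),
             matrix(rnorm(60 * 4, mean = 8), ncol = 4))
  y <- tsneEmbed(f, perplexity = 15, seed = 2, nIter = 250)
  within <- c(dist(y[1:60, ]), dist(y[61:120, ]))
  centers <- rbind(colMeans(y[1:60, ]), colMeans(y[61:120, ]))
  expect_gt(sqrt(sum((centers[1, ] - centers[2, ])^2)), median(within))
})

test_that("a short SimCLR run decreases the contrastive loss and is
           seed-reproducible", {
  ds <- tinyDataset(nClasses = 7, nPerClass = 30, size = 32, seed = 15,
                    testFraction = 0.2)
  cfg <- simclrConfig(batchSize = 56, inputSize = 32, learningRate = 0.2,
                      warmupEpochs = 3, totalEpochs = 12, temperature = 0.5,
                      seed = 5)
  res <- sharedRun("simclrDesk", trainSimCLR(ds, cfg))
  expect_equal(nrow(res$history), 12)
  expect_lt(res$history$train_loss[12], res$history$train_loss[1])

  cfg2 <- simclrConfig(batchSize = 16, inputSize = 16, warmupEpochs = 1,
                       totalEpochs = 2, seed = 5)
  ds2 <- tinyDataset(nClasses = 2, nPerClass = 10, size = 16, seed = 15,
                     testFraction = 0.2)
  h1 <- trainSimCLR(ds2, cfg2)$history
  h2 <- trainSimCLR(ds2, cfg2)$history
  expect_equal(h1, h2, tolerance = 1e-12)
})
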