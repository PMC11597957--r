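#' SimCLR-style training configuration
#'
#' In-batch NT-Xent contrastive training with a LARS optimizer and a linear
#' warmup followed by cosine annealing. Defaults follow the published
#' configuration: batch 256, input 32 x 32, learning rate 0.2, weight decay
#' 1e-6, 10 warmup epochs, 500 total epochs, temperature 0.5, t-SNE
#' perplexity 50.
#'
#' @param batchSize Batch size (>= 2, default 256).
#' @param inputSize Input image side (default 32).
#' @param learningRate Peak LARS learning rate (default 0.2).
#' @param weightDecay L2 coefficient (default 1e-6).
#' @param warmupEpochs Linear warmup epochs (default 10).
#' @param totalEpochs Total epochs (default 500).
#' @param temperature NT-Xent temperature (default 0.5).
#' @param tsnePerplexity Perplexity for the embedding export (default 50).
#' @param trustCoefficient LARS trust coefficient (default 0.001).
#' @param projDim Projection-head output width (default 128).
#' @param seed Integer seed.
#' @return A validated list of class "simclrConfig".
#' @export
simclrConfig <- function(batchSize = 256L, inputSize = 32L,
                         learningRate = 0.2, weightDecay = 1e-6,
                         warmupEpochs = 10L, totalEpochs = 500L,
                         temperature = 0.5, tsnePerplexity = 50,
                         trustCoefficient = 0.001, projDim = 128L,
                         seed = 1L) {
  stopifnot(batchSize >= 2, warmupEpochs < totalEpochs, temperature > 0,
            learningRate > 0, inputSize >= 8)
  structure(list(batchSize = as.integer(batchSize),
                 inputSize = as.integer(inputSize),
                 learningRate = learningRate, weightDecay = weightDecay,
                 warmupEpochs = as.integer(warmupEpochs),
                 totalEpochs = as.integer(totalEpochs),
                 temperature = temperature, tsnePerplexity = tsnePerplexity,
                 trustCoefficient = trustCoefficient,
                 projDim = as.integer(projDim), seed = as.integer(seed)),
            class = "simclrConfig")
}

#' In-batch NT-Xent loss
#'
#' Standard normalized temperature-scaled cross-entropy over a batch of 2B
#' unit-norm projections where rows 2i-1 and 2i are the two views of item i:
#' for each anchor the positive is its paired view and the negatives are the
#' other 2B-2 rows (self excluded); the loss is the mean over the 2B anchors
#' of \eqn{-\ln[\exp(s_{pos}/\tau) / \sum \exp(s/\tau)]}.
#'
#' @param projections 2B x d matrix of unit-norm rows, view pairs adjacent.
#' @param tau Positive temperature.
#' @return Non-negative scalar loss.
#' @examples
#' z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
#' ntxentInBatchLoss(z, tau = 1) # log(1 + 2 * exp(-1))
#' @export
ntxentInBatchLoss <- function(projections, tau) {
  ntxentGrad(projections, tau, wantGrad = FALSE, normalize = FALSE)$loss
}

# NT-Xent with optional internal row normalization and gradient.
ntxentGrad <- function(z, tau, wantGrad = TRUE, normalize = TRUE) {
  if (tau <= 0) stop("tau must be positive")
  n <- nrow(z)
  if (n %% 2L != 0L) stop("projections must have an even number of rows")
  if (normalize) {
    nrm <- sqrt(pmax(rowSums(z^2), 1e-12))
    zn <- z / nrm
  } else {
    zn <- z
  }
  pos <- ifelse(seq_len(n) %% 2L == 1L, seq_len(n) + 1L, seq_len(n) - 1L)
  s <- zn %*% t(zn) / tau
  diag(s) <- -Inf
  mx <- apply(s, 1, max)
  ex <- exp(s - mx)
  Z <- rowSums(ex)
  spos <- s[cbind(seq_len(n), pos)]
  loss <- mean(-(spos - mx) + log(Z))
  if (!wantGrad) return(list(loss = loss))
  P <- ex / Z
  G <- P
  G[cbind(seq_len(n), pos)] <- G[cbind(seq_len(n), pos)] - 1
  diag(G) <- 0
  dzn <- ((G + t(G)) %*% zn) / (n * tau)
  if (normalize) {
    proj <- rowSums(dzn * zn)
    dz <- (dzn - zn * proj) / nrm
  } else {
    dz <- dzn
  }
  list(loss = loss, dz = dz)
}

#' Train a SimCLR-style encoder
#'
#' Two augmented views per image pass through a single encoder plus a
#' two-layer projection head; the in-batch NT-Xent loss is minimized with
#' LARS under a linear-warmup/cosine-annealing schedule. No downstream
#' classifier is trained.
#'
#' @param dataset A \code{\linkS4class{LabeledImageSet}}.
#' @param cfg A \code{\link{simclrConfig}}.
#' @param encConfig Encoder architecture; default a resnet8 backbone with
#'   the first-convolution modification (kernel 3, stride 1, no padding).
#' @param verbose Print per-epoch progress.
#' @return list(encoder, head, history = data.frame(epoch, train_loss)).
#' @export
trainSimCLR <- function(dataset, cfg, encConfig = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "simclrConfig"))
  if (is.null(encConfig))
    encConfig <- encoderConfig("resnet8", featureDim = 64L, numBnSplits = 1L,
                               l2NormalizeOutput = FALSE, simclrStem = TRUE)
  if (encConfig$l2NormalizeOutput)
    stop("SimCLR encoder must emit raw (non-normalized) features; ",
         "the projection head output is normalized inside the loss")
  tr <- trainIndices(dataset)
  if (length(tr) < cfg$batchSize) {
    # clamp to the largest even batch the split allows
    cfg$batchSize <- max(2L, (length(tr) %/% 2L) * 2L)
  }
  set.seed(cfg$seed)
  enc <- buildEncoder(encConfig)
  head <- buildProjectionHead(encConfig$featureDim, encConfig$featureDim,
                              cfg$projDim)
  augCfg <- augmentationConfig(cropSize = cfg$inputSize)
  optState <- NULL
  history <- data.frame(epoch = integer(0), train_loss = numeric(0))

  for (epoch in seq_len(cfg$totalEpochs) - 1L) {
    lr <- warmupCosineLR(epoch, cfg$learningRate, cfg$warmupEpochs,
                         cfg$totalEpochs)
    perm <- sample(tr)
    nBatches <- length(perm) %/% cfg$batchSize
    lossSum <- 0
    for (bi in seq_len(nBatches)) {
      idx <- perm[((bi - 1L) * cfg$batchSize + 1L):(bi * cfg$batchSize)]
      tv <- makeTwoViewBatch(dataset, idx, augCfg)
      # interleave views: rows 2i-1, 2i are the pair for item i
      B <- length(idx)
      d <- dim(tv$viewA)
      x <- array(0, c(d[1], d[2], d[3], 2L * B))
      x[, , , seq(1L, 2L * B, 2L)] <- tv$viewA
      x[, , , seq(2L, 2L * B, 2L)] <- tv$viewB
      fe <- encoderForward(enc, x, training = TRUE)
      enc <- fe$encoder
      fh <- nnForward(head, fe$features, training = TRUE)
      head <- fh$mod
      lg <- ntxentGrad(fh$out, cfg$temperature)
      lossSum <- lossSum + lg$loss

      bh <- nnBackward(head, fh$cache, lg$dz)
      be <- nnBackward(enc@net, fe$cache, bh$dx)
      params <- c(prefixNames(nnParams(enc@net), "enc/"),
                  prefixNames(nnParams(head), "head/"))
      grads <- c(prefixNames(nnFlattenGrads(enc@net, be$grads), "enc/"),
                 prefixNames(nnFlattenGrads(head, bh$grads), "head/"))
      st <- larsStep(params, grads, lr, weightDecay = cfg$weightDecay,
                     trustCoefficient = cfg$trustCoefficient,
                     state = optState)
      optState <- st$state
      enc@net <- nnSetParams(enc@net, stripPrefix(st$params, "enc/"))
      head <- nnSetParams(head, stripPrefix(st$params, "head/"))
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = lossSum /
                                           max(nBatches, 1)))
    if (verbose)
      message(sprintf("epoch %3d  lr %.4f  ntxent %.4f", epoch, lr,
                      lossSum / max(nBatches, 1)))
  }
  list(encoder = enc, head = head, history = history)
}

prefixNames <- function(x, p) {
  names(x) <- paste0(p, names(x))
  x
}

stripPrefix <- function(x, p) {
  keep <- startsWith(names(x), p)
  x <- x[keep]
  names(x) <- substring(names(x), nchar(p) + 1L)
  x
}

#' Exact t-SNE embedding of feature vectors
#'
#' A 2-d t-distributed stochastic neighbour embedding computed by the exact
#' O(N^2) algorithm: per-point Gaussian bandwidths calibrated to the target
#' perplexity by bisection, symmetrized input affinities, Student-t output
#' kernel, gradient descent with early exaggeration and momentum. Requires
#' N > 3 * perplexity.
#'
#' @param features N x d numeric matrix.
#' @param perplexity Target perplexity (default 50).
#' @param seed Integer seed for the random initialization.
#' @param nIter Gradient-descent iterations (default 400).
#' @return N x 2 matrix of embedding coordinates.
#' @export
tsneEmbed <- function(features, perplexity = 50, seed = 1L, nIter = 400L) {
  n <- nrow(features)
  if (n <= 3 * perplexity)
    stop("t-SNE requires N > 3 * perplexity (N = ", n, ", perplexity = ",
         perplexity, ")")
  D2 <- as.matrix(stats::dist(features))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf
    hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    vel <- matrix(0, n, 2)
    for (it in seq_len(nIter)) {
      exag <- if (it <= 100) 12 else 1
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (exag * P - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (it <= 250) 0.5 else 0.8
      vel <- mom * vel - 200 * grad
      Y <- Y + vel
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
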