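#' Momentum-contrast training configuration
#'
#' Hyperparameter surface of the momentum-contrast training loop. The
#' defaults follow the best-performing published configuration at image
#' resolution 96: batch 128, learning rate 0.3, EMA momentum 0.99, softmax
#' temperature 0.1, KNN monitor with K = 200 and temperature 0.1.
#'
#' @param batchSize Contrastive batch size; must be divisible by the
#'   encoder's batch-norm splits (default 128).
#' @param learningRate Peak SGD learning rate, cosine-annealed to 0 over
#'   \code{epochs} (default 0.3).
#' @param sgdMomentum,weightDecay SGD heavy-ball momentum and L2 decay
#'   (defaults 0.9, 1e-4).
#' @param momentum EMA coefficient m for the key encoder (default 0.99).
#' @param temperature Contrastive softmax temperature tau (default 0.1).
#' @param epochs Training epochs.
#' @param queueSize Negative-feature queue length (default 4096).
#' @param knnK,knnTemperature KNN-monitor neighbours and temperature
#'   (defaults 200, 0.1).
#' @param imageResolution Input image side in pixels (default 96).
#' @param cropScale Random-resized-crop area range (default c(0.2, 1)).
#' @param seed Integer seed governing initialization, augmentation and
#'   shuffling.
#' @return A validated list of class "mocoTrainConfig".
#' @export
mocoTrainConfig <- function(batchSize = 128L, learningRate = 0.3,
                            sgdMomentum = 0.9, weightDecay = 1e-4,
                            momentum = 0.99, temperature = 0.1,
                            epochs = 200L, queueSize = 4096L,
                            knnK = 200L, knnTemperature = 0.1,
                            imageResolution = 96L, cropScale = c(0.2, 1),
                            seed = 1L) {
  stopifnot(batchSize >= 1, learningRate > 0, momentum >= 0, momentum <= 1,
            temperature > 0, epochs >= 1, queueSize >= 1, knnK >= 1,
            knnTemperature > 0, imageResolution >= 8)
  structure(list(batchSize = as.integer(batchSize),
                 learningRate = learningRate, sgdMomentum = sgdMomentum,
                 weightDecay = weightDecay, momentum = momentum,
                 temperature = temperature, epochs = as.integer(epochs),
                 queueSize = as.integer(queueSize), knnK = as.integer(knnK),
                 knnTemperature = knnTemperature,
                 imageResolution = as.integer(imageResolution),
                 cropScale = cropScale, seed = as.integer(seed)),
            class = "mocoTrainConfig")
}

#' Queue-denominator contrastive loss
#'
#' The per-example loss is the temperature-scaled cross-entropy
#' \deqn{L_q = -\ln \frac{e^{q\cdot k^+/\tau}}
#'   {\sum_{i=0}^{K} e^{q\cdot k_i/\tau}}}
#' where \eqn{k_0 = k^+} is the positive key and \eqn{k_1..k_K} are the
#' queue entries (the negatives); the batch loss is the mean. Equivalent to
#' (1+K)-way softmax cross-entropy with the positive at index 0.
#'
#' @param q B x d matrix of unit-norm query features.
#' @param kPos B x d matrix of unit-norm positive-key features, row-paired
#'   with \code{q}.
#' @param queue K x d matrix of unit-norm negative features (K may be 0).
#' @param tau Positive temperature.
#' @return The mean per-example loss (non-negative scalar).
#' @examples
#' q <- matrix(c(1, 0), 1)
#' contrastiveLoss(q, q, matrix(c(0, 1), 1), tau = 1) # log(1 + exp(-1))
#' @export
contrastiveLoss <- function(q, kPos, queue, tau) {
  contrastiveLossGrad(q, kPos, queue, tau, wantGrad = FALSE)$loss
}

# Loss plus gradient with respect to q (keys and queue carry no gradient).
contrastiveLossGrad <- function(q, kPos, queue, tau, wantGrad = TRUE) {
  if (tau <= 0) stop("tau must be positive")
  if (!is.matrix(q)) q <- matrix(q, nrow = 1)
  if (!is.matrix(kPos)) kPos <- matrix(kPos, nrow = 1)
  if (ncol(q) != ncol(kPos) || nrow(q) != nrow(kPos))
    stop("q and kPos must have matching dimensions")
  K <- if (is.null(queue) || length(queue) == 0) 0L else nrow(queue)
  if (K > 0 && ncol(queue) != ncol(q))
    stop("queue feature dimension mismatch")
  B <- nrow(q)
  lpos <- rowSums(q * kPos) / tau
  logits <- if (K > 0) cbind(lpos, q %*% t(queue) / tau) else
    matrix(lpos, ncol = 1)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  loss <- mean(-(lpos - mx) + log(Z))
  if (!wantGrad) return(list(loss = loss))
  p <- ex / Z
  dq <- (p[, 1] - 1) * kPos
  if (K > 0) dq <- dq + p[, -1, drop = FALSE] %*% queue
  dq <- dq / (B * tau)
  list(loss = loss, dq = dq)
}

#' Exponential-moving-average parameter update
#'
#' Updates every key parameter as
#' \eqn{\theta_k \leftarrow m\,\theta_k + (1 - m)\,\theta_q}. With
#' \code{m = 1} the key parameters are unchanged; with \code{m = 0} they
#' become an exact copy of the query parameters.
#'
#' @param queryParams,keyParams Named lists of numeric arrays with matching
#'   shapes (as returned by the encoder's parameter accessor).
#' @param m EMA coefficient in [0, 1].
#' @return The updated key parameter list.
#' @export
emaUpdate <- function(queryParams, keyParams, m) {
  stopifnot(m >= 0, m <= 1)
  for (nm in names(keyParams)) {
    qp <- queryParams[[nm]]
    if (is.null(qp) || !identical(dim(keyParams[[nm]]), dim(qp)) ||
        length(keyParams[[nm]]) != length(qp))
      stop("parameter shape mismatch at ", nm)
    keyParams[[nm]] <- m * keyParams[[nm]] + (1 - m) * qp
  }
  keyParams
}

#' Initialize a momentum-contrast state
#'
#' The key encoder starts as an exact copy of the query encoder and the
#' queue is filled with random unit vectors (drawn from the current RNG) to
#' avoid degenerate all-equal similarities at step 0.
#'
#' @param queryEncoder An \code{\linkS4class{Encoder}}.
#' @param queueSize Queue length K.
#' @param momentum EMA coefficient m.
#' @param temperature Softmax temperature tau.
#' @return A \code{\linkS4class{MoCoState}}.
#' @export
mocoState <- function(queryEncoder, queueSize, momentum = 0.99,
                      temperature = 0.1) {
  d <- queryEncoder@config$featureDim
  queue <- matrix(stats::rnorm(queueSize * d), queueSize, d)
  queue <- queue / sqrt(rowSums(queue^2))
  methods::new("MoCoState", queryEncoder = queryEncoder,
               keyEncoder = queryEncoder, queue = queue, queuePtr = 0L,
               momentum = momentum, temperature = temperature)
}

#' FIFO enqueue of new key features
#'
#' Ring-buffer semantics: the new keys overwrite queue rows starting at the
#' write pointer, wrapping at the end; the pointer advances by the batch
#' size modulo the queue size. The queue size is invariant.
#'
#' @param state A \code{\linkS4class{MoCoState}}.
#' @param newKeys B x d matrix of unit-norm key features, B <= queue size.
#' @return The updated state.
#' @export
enqueueDequeue <- function(state, newKeys) {
  if (!is.matrix(newKeys)) newKeys <- matrix(newKeys, nrow = 1)
  K <- nrow(state@queue)
  B <- nrow(newKeys)
  if (B > K) stop("batch of ", B, " keys exceeds queue size ", K)
  rows <- ((state@queuePtr + seq_len(B) - 1L) %% K) + 1L
  state@queue[rows, ] <- newKeys
  state@queuePtr <- as.integer((state@queuePtr + B) %% K)
  state
}

#' Train a momentum-contrast encoder
#'
#' The full training loop: per epoch, two-view augmented batches are drawn
#' from the training split; the query encoder embeds view A and the key
#' (momentum) encoder embeds view B without gradient tracking; the
#' queue-denominator contrastive loss is computed against the current
#' negative queue; the query encoder takes an SGD-with-momentum step under a
#' cosine-annealed learning rate; the key encoder follows by exponential
#' moving average; and the new keys are enqueued. After every epoch the
#' KNN monitor classifies the test split from query-encoder features.
#' Batches that would leave fewer than \code{batchSize} images (and hence
#' break batch-norm split divisibility) are dropped.
#'
#' @param dataset A \code{\linkS4class{LabeledImageSet}}.
#' @param encConfig An \code{\link{encoderConfig}}.
#' @param cfg A \code{\link{mocoTrainConfig}}.
#' @param verbose Print per-epoch progress (default FALSE).
#' @return list(encoder = trained query \code{\linkS4class{Encoder}},
#'   history = data.frame(epoch, train_loss, knn_accuracy_pct),
#'   state = final \code{\linkS4class{MoCoState}}).
#' @export
trainMoCo <- function(dataset, encConfig, cfg, verbose = FALSE) {
  stopifnot(inherits(encConfig, "encoderConfig"),
            inherits(cfg, "mocoTrainConfig"))
  tr <- trainIndices(dataset)
  if (length(tr) == 0) stop("empty training split")
  if (cfg$batchSize %% encConfig$numBnSplits != 0L)
    stop("batchSize must be divisible by numBnSplits")
  if (length(tr) < cfg$batchSize)
    stop("training split smaller than one batch")

  set.seed(cfg$seed)
  queryEnc <- buildEncoder(encConfig)
  state <- mocoState(queryEnc, cfg$queueSize, cfg$momentum, cfg$temperature)
  keyEnc <- state@keyEncoder

  augCfg <- augmentationConfig(cropSize = cfg$imageResolution,
                               cropScale = cfg$cropScale)
  knnCfg <- knnConfig(k = cfg$knnK, temperature = cfg$knnTemperature,
                      numClasses = nClasses(dataset))
  optState <- NULL
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        knn_accuracy_pct = numeric(0))

  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- cosineLR(epoch, cfg$learningRate, cfg$epochs)
    perm <- sample(tr)
    nBatches <- length(perm) %/% cfg$batchSize
    lossSum <- 0
    for (bi in seq_len(nBatches)) {
      idx <- perm[((bi - 1L) * cfg$batchSize + 1L):(bi * cfg$batchSize)]
      tv <- makeTwoViewBatch(dataset, idx, augCfg)
      fq <- encoderForward(queryEnc, tv$viewA, training = TRUE)
      queryEnc <- fq$encoder
      fk <- encoderForward(keyEnc, tv$viewB, training = TRUE)
      keyEnc <- fk$encoder
      lg <- contrastiveLossGrad(fq$features, fk$features, state@queue,
                                cfg$temperature)
      lossSum <- lossSum + lg$loss

      bk <- nnBackward(queryEnc@net, fq$cache, lg$dq)
      grads <- nnFlattenGrads(queryEnc@net, bk$grads)
      params <- nnParams(queryEnc@net)
      st <- sgdMomentumStep(params, grads, optState, lr,
                            momentum = cfg$sgdMomentum,
                            weightDecay = cfg$weightDecay)
      optState <- st$state
      queryEnc@net <- nnSetParams(queryEnc@net, st$params)

      keyEnc@net <- nnSetParams(
        keyEnc@net,
        emaUpdate(st$params, nnParams(keyEnc@net), cfg$momentum))
      state <- enqueueDequeue(state, fk$features)
    }
    acc <- evaluateKnnAccuracy(queryEnc, dataset, knnCfg,
                               size = cfg$imageResolution)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = lossSum / max(nBatches, 1),
                                knn_accuracy_pct = acc))
    if (verbose)
      message(sprintf("epoch %3d  lr %.4f  loss %.4f  knn %.2f%%",
                      epoch, lr, lossSum / max(nBatches, 1), acc))
  }
  state@queryEncoder <- queryEnc
  state@keyEncoder <- keyEnc
  list(encoder = queryEnc, history = history, state = state)
}
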