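#' Supervised baseline configuration
#'
#' Transfer-learning-style supervised classifier: a residual-network
#' backbone whose final fully connected layer is replaced by a
#' class-count output, trained with Adam on cross-entropy. Training-split
#' augmentation is random rotation, horizontal flip, resize and center
#' crop, then ImageNet normalization; evaluation uses the deterministic
#' transform. The published benchmark initialized the backbone from
#' ImageNet-pretrained weights; no offline weight source ships with this
#' package, so \code{pretrained = TRUE} raises an error and the default is
#' random initialization.
#'
#' @param arch Backbone architecture (default "resnet50"; smaller variants
#'   such as "resnet8" suit desk-scale experiments).
#' @param pretrained Request pretrained weights (unsupported offline;
#'   default FALSE).
#' @param lr Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 20).
#' @param batchSize Batch size (default 32).
#' @param rotationDegrees Random-rotation half-range in degrees (default 10).
#' @param pHflip Horizontal-flip probability (default 0.5).
#' @param resize Input side in pixels (default 224).
#' @param mean,std Normalization statistics (ImageNet defaults).
#' @param seed Integer seed.
#' @return A validated list of class "supervisedConfig".
#' @export
supervisedConfig <- function(arch = "resnet50", pretrained = FALSE,
                             lr = 0.001, epochs = 20L, batchSize = 32L,
                             rotationDegrees = 10, pHflip = 0.5,
                             resize = 224L, mean = imagenetMean(),
                             std = imagenetStd(), seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batchSize >= 1, resize >= 8,
            rotationDegrees >= 0, pHflip >= 0, pHflip <= 1)
  structure(list(arch = arch, pretrained = pretrained, lr = lr,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 rotationDegrees = rotationDegrees, pHflip = pHflip,
                 resize = as.integer(resize), mean = mean, std = std,
                 seed = as.integer(seed)),
            class = "supervisedConfig")
}

# Rotation by a uniform angle, resize, optional flip, normalize.
supervisedTransform <- function(img, cfg) {
  if (cfg$rotationDegrees > 0) {
    ang <- stats::runif(1, -cfg$rotationDegrees, cfg$rotationDegrees)
    d <- dim(img)
    rot <- EBImage::rotate(EBImage::Image(img, colormode = "Color"), ang,
                           output.dim = c(d[1], d[2]), bg.col = "black")
    img <- EBImage::imageData(rot)
    dim(img) <- d
  }
  img <- resizeBilinear(img, cfg$resize, cfg$resize)
  if (cfg$pHflip > 0 && stats::runif(1) < cfg$pHflip)
    img <- img[, dim(img)[2]:1, , drop = FALSE]
  normalizeChannels(pmin(pmax(img, 0), 1), cfg$mean, cfg$std)
}

# Mean softmax cross-entropy and its logit gradient; labels are 0-based.
softmaxCrossEntropy <- function(logits, labels) {
  n <- nrow(logits)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  tgt <- cbind(seq_len(n), labels + 1L)
  loss <- mean(-(logits[tgt] - mx) + log(Z))
  P <- ex / Z
  P[tgt] <- P[tgt] - 1
  list(loss = loss, dlogits = P / n)
}

#' Train the supervised classification baseline
#'
#' Builds the configured backbone with its output layer sized to the
#' dataset's class count, trains with Adam on cross-entropy over the
#' training split, logs per-epoch training loss and held-out (test-split)
#' accuracy, and returns the parameters of the best-accuracy epoch.
#'
#' @param dataset A \code{\linkS4class{LabeledImageSet}}.
#' @param cfg A \code{\link{supervisedConfig}}.
#' @param verbose Print per-epoch progress.
#' @return list(classifier = \code{\linkS4class{Encoder}} whose output layer
#'   emits class logits (best epoch), history = data.frame(epoch,
#'   train_loss, test_accuracy_pct), report =
#'   \code{\linkS4class{ClassificationReport}} of the best classifier on
#'   the test split).
#' @export
trainSupervised <- function(dataset, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "supervisedConfig"))
  k <- nClasses(dataset)
  if (k < 2) stop("need at least 2 classes")
  tr <- trainIndices(dataset)
  te <- testIndices(dataset)
  if (length(tr) == 0 || length(te) == 0) stop("empty split")

  set.seed(cfg$seed)
  encCfg <- encoderConfig(cfg$arch, featureDim = k, numBnSplits = 1L,
                          l2NormalizeOutput = FALSE,
                          pretrained = cfg$pretrained)
  net <- buildEncoder(encCfg)
  optState <- NULL
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        test_accuracy_pct = numeric(0))
  best <- list(acc = -1, params = NULL)
  labels <- imageLabels(dataset)

  for (epoch in seq_len(cfg$epochs) - 1L) {
    perm <- sample(tr)
    nBatches <- max(1L, length(perm) %/% cfg$batchSize)
    lossSum <- 0
    for (bi in seq_len(nBatches)) {
      idx <- perm[((bi - 1L) * cfg$batchSize + 1L):
                    min(bi * cfg$batchSize, length(perm))]
      imgs <- lapply(idx, function(i)
        supervisedTransform(getImage(dataset, i), cfg))
      x <- stackImages(imgs)
      fw <- encoderForward(net, x, training = TRUE)
      net <- fw$encoder
      ce <- softmaxCrossEntropy(fw$features, labels[idx])
      lossSum <- lossSum + ce$loss
      bk <- nnBackward(net@net, fw$cache, ce$dlogits)
      grads <- nnFlattenGrads(net@net, bk$grads)
      st <- adamStep(nnParams(net@net), grads, optState, cfg$lr)
      optState <- st$state
      net@net <- nnSetParams(net@net, st$params)
    }
    pred <- predictSupervised(net, dataset, te, cfg)
    acc <- 100 * mean(pred == labels[te])
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = lossSum / nBatches,
                                         test_accuracy_pct = acc))
    if (acc > best$acc) best <- list(acc = acc, params = nnParams(net@net),
                                     net = net)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  test acc %.2f%%", epoch,
                      lossSum / nBatches, acc))
  }
  net <- best$net
  net@net <- nnSetParams(net@net, best$params)
  pred <- predictSupervised(net, dataset, te, cfg)
  report <- classificationReport(pred, labels[te], classNames(dataset))
  list(classifier = net, history = history, report = report)
}

# Eval-mode argmax predictions (0-based) for dataset indices.
predictSupervised <- function(net, dataset, indices, cfg, batchSize = 64L) {
  logits <- encodeImages(net, dataset, indices, cfg$resize, batchSize,
                         mean = cfg$mean, std = cfg$std)
  max.col(logits, ties.method = "first") - 1L
}

#' Compare the supervised baseline with momentum-contrast + KNN
#'
#' Trains both paths on the same dataset and reports overall accuracy plus
#' per-class recall for each method, one row per method and one column per
#' class.
#'
#' @param dataset A \code{\linkS4class{LabeledImageSet}}.
#' @param supCfg A \code{\link{supervisedConfig}}.
#' @param mocoEncConfig An \code{\link{encoderConfig}} for the contrastive
#'   path.
#' @param mocoCfg A \code{\link{mocoTrainConfig}}.
#' @return data.frame with columns method, overall_accuracy_pct, and one
#'   recall column per class.
#' @export
compareSupervisedVsUnsupervised <- function(dataset, supCfg, mocoEncConfig,
                                            mocoCfg) {
  sup <- trainSupervised(dataset, supCfg)
  moco <- trainMoCo(dataset, mocoEncConfig, mocoCfg)

  te <- testIndices(dataset)
  labels <- imageLabels(dataset)
  knnCfg <- knnConfig(k = mocoCfg$knnK, temperature = mocoCfg$knnTemperature,
                      numClasses = nClasses(dataset))
  tr <- trainIndices(dataset)
  bank <- memoryBank(encodeImages(moco$encoder, dataset, tr,
                                  mocoCfg$imageResolution),
                     labels[tr], nClasses(dataset))
  qf <- encodeImages(moco$encoder, dataset, te, mocoCfg$imageResolution)
  mocoPred <- knnPredict(qf, bank, knnCfg)$labels
  supPred <- predictSupervised(sup$classifier, dataset, te, supCfg)

  mkRow <- function(method, pred) {
    rep <- classificationReport(pred, labels[te], classNames(dataset))
    row <- data.frame(method = method,
                      overall_accuracy_pct = rep@accuracy)
    for (i in seq_len(nClasses(dataset)))
      row[[classNames(dataset)[i]]] <- rep@perClass$recall[i]
    row
  }
  rbind(mkRow("supervised", supPred), mkRow("moco_knn", mocoPred))
}
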