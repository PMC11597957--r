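#' KNN monitor configuration
#'
#' @param k Number of nearest neighbours considered (default 200; clamped to
#'   the memory-bank size at prediction time).
#' @param temperature Softmax temperature applied to cosine similarities
#'   (default 0.1).
#' @param numClasses Number of classes.
#' @return A validated list of class "knnConfig".
#' @export
knnConfig <- function(k = 200L, temperature = 0.1, numClasses) {
  stopifnot(k >= 1, temperature > 0, numClasses >= 1)
  structure(list(k = as.integer(k), temperature = temperature,
                 numClasses = as.integer(numClasses)), class = "knnConfig")
}

#' Construct a memory bank
#'
#' @param features N x d matrix of unit-norm feature rows.
#' @param labels Integer vector of 0-based class indices.
#' @param numClasses Number of classes.
#' @return A \code{\linkS4class{MemoryBank}}.
#' @export
memoryBank <- function(features, labels, numClasses) {
  methods::new("MemoryBank", features = features,
               labels = as.integer(labels), numClasses = as.integer(numClasses))
}

#' Temperature-weighted K-nearest-neighbour prediction
#'
#' For each query: cosine similarities to every memory-bank row (all rows
#' unit-norm, so the dot product), the top-k by similarity with ties broken
#' by lower bank index, weights \eqn{w_i = \exp(s_i / temperature)}, per-class
#' scores as the weighted sum of the neighbours' one-hot labels, and the
#' predicted label as the arg-max score (ties resolved to the smallest class
#' index). Scores are normalized to probabilities per query.
#'
#' @param queries Q x d matrix of unit-norm query features.
#' @param bank A \code{\linkS4class{MemoryBank}}.
#' @param cfg A \code{\link{knnConfig}}.
#' @return list(labels = integer Q-vector of 0-based predictions,
#'   scores = Q x numClasses matrix of class probabilities).
#' @export
knnPredict <- function(queries, bank, cfg) {
  stopifnot(inherits(cfg, "knnConfig"))
  N <- nrow(bank@features)
  if (N == 0) stop("memory bank is empty")
  if (ncol(queries) != ncol(bank@features))
    stop("feature dimension mismatch between queries and bank")
  k <- min(cfg$k, N)
  C <- cfg$numClasses
  sim <- queries %*% t(bank@features)
  Q <- nrow(queries)
  labels <- integer(Q)
  scores <- matrix(0, Q, C)
  for (qi in seq_len(Q)) {
    # radix order is stable: equal similarities keep lower bank index first
    ord <- order(sim[qi, ], decreasing = TRUE, method = "radix")[seq_len(k)]
    w <- exp(sim[qi, ord] / cfg$temperature)
    sc <- numeric(C)
    agg <- rowsum(w, bank@labels[ord])
    sc[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    labels[qi] <- which.max(sc) - 1L # first maximum = smallest class index
    scores[qi, ] <- sc / sum(sc)
  }
  list(labels = labels, scores = scores)
}

#' KNN-monitor accuracy of an encoder on a dataset
#'
#' Builds the memory bank from eval-transformed training-split features of
#' the encoder, predicts every test-split image with
#' \code{\link{knnPredict}}, and returns the percentage of correct
#' predictions.
#'
#' @param encoder An \code{\linkS4class{Encoder}} (used in evaluation mode).
#' @param dataset A \code{\linkS4class{LabeledImageSet}} with non-empty
#'   train and test splits.
#' @param cfg A \code{\link{knnConfig}}.
#' @param size Evaluation image side in pixels.
#' @param batchSize Forward-pass batch size (default 64).
#' @return Accuracy in percent.
#' @export
evaluateKnnAccuracy <- function(encoder, dataset, cfg, size,
                                batchSize = 64L) {
  tr <- trainIndices(dataset)
  te <- testIndices(dataset)
  if (length(tr) == 0 || length(te) == 0)
    stop("dataset must have non-empty train and test splits")
  bankF <- encodeImages(encoder, dataset, tr, size, batchSize)
  bank <- memoryBank(bankF, imageLabels(dataset)[tr], nClasses(dataset))
  queries <- encodeImages(encoder, dataset, te, size, batchSize)
  pred <- knnPredict(queries, bank, cfg)
  100 * mean(pred$labels == imageLabels(dataset)[te])
}

#' Per-class classification report
#'
#' Computes per-class precision, recall and F1 (harmonic mean, 0 when
#' undefined), per-class support, overall accuracy and macro averages from
#' predicted and true 0-based labels.
#'
#' @param predicted,truth Equal-length integer vectors of 0-based labels.
#' @param classNames Character vector naming classes 0..k-1.
#' @return A \code{\linkS4class{ClassificationReport}}.
#' @examples
#' classificationReport(c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L), c("A", "B"))
#' @export
classificationReport <- function(predicted, truth, classNames) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (length(predicted) == 0) stop("empty input")
  k <- length(classNames)
  lev <- seq_len(k) - 1L
  cm <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  tp <- diag(cm)
  predN <- colSums(cm)
  truthN <- rowSums(cm)
  precision <- ifelse(predN > 0, tp / predN, 0)
  recall <- ifelse(truthN > 0, tp / truthN, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  perClass <- data.frame(class = classNames,
                         precision = as.numeric(precision),
                         recall = as.numeric(recall),
                         f1 = as.numeric(f1),
                         support = as.integer(truthN))
  methods::new("ClassificationReport", perClass = perClass,
               accuracy = 100 * sum(tp) / length(truth),
               macroPrecision = mean(precision), macroRecall = mean(recall),
               macroF1 = mean(f1))
}
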