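#' Split batch normalization forward pass
#'
#' Normalizes a feature-map batch with *split* batch statistics: in training
#' mode the batch is partitioned into \code{numSplits} contiguous groups along
#' the sample axis and each group is normalized with its own per-channel mean
#' and (biased) variance, emulating the per-device statistics of multi-GPU
#' batch normalization on a single device. The affine parameters
#' \code{gamma}/\code{beta} are shared across splits. Running statistics are
#' aggregated as the arithmetic mean of the split statistics (variance with
#' the usual unbiased correction) and are used verbatim in evaluation mode,
#' where the layer behaves exactly like standard batch normalization.
#' With \code{numSplits = 1} the layer reduces to standard batch
#' normalization.
#'
#' @param x A numeric array of shape (H, W, C, N): feature maps for a batch
#'   of N samples with C channels.
#' @param gamma,beta Numeric vectors of length C, the shared affine scale and
#'   shift.
#' @param numSplits Number of contiguous batch splits (default 1). In
#'   training mode N must be divisible by \code{numSplits}.
#' @param training Logical; use batch statistics (TRUE) or running
#'   statistics (FALSE).
#' @param runningMean,runningVar Numeric vectors of length C holding the
#'   running statistics.
#' @param momentum Running-statistic update rate (default 0.1).
#' @param eps Variance floor (default 1e-5).
#' @return A list with \code{out} (array like \code{x}), \code{cache}
#'   (internal state for the backward pass), and the updated
#'   \code{runningMean}/\code{runningVar}.
#' @examples
#' x <- array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8))
#' r <- splitBatchNormForward(x, gamma = c(1, 1), beta = c(0, 0),
#'                            numSplits = 2, training = TRUE,
#'                            runningMean = c(0, 0), runningVar = c(1, 1))
#' dim(r$out)
#' @export
splitBatchNormForward <- function(x, gamma, beta, numSplits = 1L,
                                  training = TRUE,
                                  runningMean = NULL, runningVar = NULL,
                                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  stopifnot(length(d) == 4L, length(gamma) == d[3], length(beta) == d[3])
  C <- d[3]
  N <- d[4]
  if (is.null(runningMean)) runningMean <- rep(0, C)
  if (is.null(runningVar)) runningVar <- rep(1, C)

  if (!training) {
    out <- bn_eval_fwd(x, gamma, beta, runningMean, runningVar, eps)
    cache <- list(mode = "eval", x = x, runningMean = runningMean,
                  invstd = 1 / sqrt(runningVar + eps), gamma = gamma,
                  dims = d)
    return(list(out = out, cache = cache,
                runningMean = runningMean, runningVar = runningVar))
  }

  numSplits <- as.integer(numSplits)
  if (N %% numSplits != 0L)
    stop("batch size ", N, " is not divisible by numSplits = ", numSplits)
  perSplit <- N %/% numSplits
  M <- d[1] * d[2] * perSplit # elements per channel per split

  r <- bn_train_fwd(x, gamma, beta, numSplits, eps)
  unbias <- if (M > 1) M / (M - 1) else 1
  runningMean <- (1 - momentum) * runningMean + momentum * rowMeans(r$mus)
  runningVar <- (1 - momentum) * runningVar +
    momentum * unbias * rowMeans(r$vars)

  cache <- list(mode = "train", xhat = r$xhat, invstds = r$invstds,
                gamma = gamma, numSplits = numSplits, dims = d)
  list(out = r$out, cache = cache, runningMean = runningMean,
       runningVar = runningVar)
}

# Backward pass matching splitBatchNormForward(); internal.
splitBatchNormBackward <- function(cache, dout) {
  if (cache$mode == "eval") {
    d <- cache$dims
    HW <- d[1] * d[2]
    dy <- dout
    dim(dy) <- c(HW, d[3], d[4])
    scale <- cache$gamma * cache$invstd
    x3 <- cache$x
    dim(x3) <- c(HW, d[3], d[4])
    xhat <- sweep(sweep(x3, 2, cache$runningMean, "-"), 2, cache$invstd, "*")
    dgamma <- rowSums(colSums(dy * xhat, dims = 1L))
    dbeta <- rowSums(colSums(dy, dims = 1L))
    dx <- sweep(dy, 2, scale, "*")
    dim(dx) <- d
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  g <- bn_train_bwd(cache$xhat, cache$gamma, cache$invstds, dout,
                    cache$numSplits)
  list(dx = g$dx, dgamma = g$dgamma, dbeta = g$dbeta)
}
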