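# Optimizers operate on flat named lists of parameter arrays (nnParams()
# naming). State lists are keyed identically and created lazily.

# SGD with momentum and decoupled-from-nothing (classic L2) weight decay.
sgdMomentumStep <- function(params, grads, state, lr, momentum = 0.9,
                            weightDecay = 1e-4) {
  if (is.null(state)) state <- list(v = list())
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    v <- state$v[[nm]]
    if (is.null(v)) v <- g else v <- momentum * v + g
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, state = state)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0) {
  if (is.null(state)) state <- list(m = list(), v = list(), t = 0L)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    m <- state$m[[nm]]
    v <- state$v[[nm]]
    if (is.null(m)) m <- g * 0
    if (is.null(v)) v <- g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Layer-wise adaptive rate scaling (LARS) update
#'
#' Performs one LARS step on a flat named list of parameter arrays. For each
#' adapted parameter tensor the local learning rate is
#' \deqn{\eta_{local} = trust \cdot \|w\| / (\|g\| + wd\,\|w\|)}
#' (guarded to 1 when either norm is zero) and the update is
#' \eqn{w \leftarrow w - lr \cdot \eta_{local} (g + wd\,w)}. One-dimensional
#' parameters (biases, batch-norm scales/shifts) are excluded from both
#' adaptation and weight decay when \code{excludeBiasAndBn} is TRUE, the
#' common large-batch practice.
#'
#' @param params Named list of numeric arrays (weights).
#' @param grads Named list of gradients, keyed like \code{params}.
#' @param lr Global learning rate.
#' @param weightDecay L2 coefficient (default 1e-6).
#' @param trustCoefficient LARS trust coefficient (default 0.001).
#' @param momentum Heavy-ball momentum (default 0.9).
#' @param state Optimizer state from a previous call, or NULL.
#' @param excludeBiasAndBn Exclude 1-d parameters from adaptation/decay.
#' @return list(params, state) with updated parameters.
#' @export
larsStep <- function(params, grads, lr, weightDecay = 1e-6,
                     trustCoefficient = 0.001, momentum = 0.9, state = NULL,
                     excludeBiasAndBn = TRUE) {
  if (is.null(state)) state <- list(v = list())
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (any(!is.finite(g))) stop("non-finite gradient for parameter ", nm)
    w <- params[[nm]]
    adapted <- !(excludeBiasAndBn && is.null(dim(w)))
    if (adapted) {
      g <- g + weightDecay * w
      wn <- sqrt(sum(w^2))
      gn <- sqrt(sum(g^2))
      local <- if (wn > 0 && gn > 0) trustCoefficient * wn / gn else 1
    } else {
      local <- 1
    }
    v <- state$v[[nm]]
    if (is.null(v)) v <- g * 0
    v <- momentum * v + lr * local * g
    state$v[[nm]] <- v
    params[[nm]] <- w - v
  }
  list(params = params, state = state)
}

# Cosine-annealed learning rate without warmup (momentum-contrast schedule).
cosineLR <- function(epoch, baseLR, totalEpochs) {
  baseLR * 0.5 * (1 + cos(pi * epoch / totalEpochs))
}

#' Linear-warmup plus cosine-annealing learning-rate schedule
#'
#' Epochs are 0-based. During the first \code{warmupEpochs} epochs the rate
#' ramps linearly from \code{baseLR / warmupEpochs} up to \code{baseLR}
#' (reached exactly at \code{epoch == warmupEpochs}); afterwards it follows
#' a half-cosine decay to 0 at \code{totalEpochs}.
#'
#' @param epoch 0-based epoch index, in \code{[0, totalEpochs)}.
#' @param baseLR Peak learning rate.
#' @param warmupEpochs Number of linear warmup epochs.
#' @param totalEpochs Total training epochs.
#' @return The learning rate for that epoch (scalar).
#' @examples
#' warmupCosineLR(10, 0.2, 10, 500) # == 0.2 at the warmup/cosine junction
#' @export
warmupCosineLR <- function(epoch, baseLR, warmupEpochs, totalEpochs) {
  if (epoch < 0 || epoch >= totalEpochs)
    stop("epoch must lie in [0, totalEpochs)")
  if (epoch < warmupEpochs)
    return(baseLR * (epoch + 1) / warmupEpochs)
  baseLR * 0.5 * (1 + cos(pi * (epoch - warmupEpochs) /
                            (totalEpochs - warmupEpochs)))
}
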