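#' @useDynLib emoco, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal layer framework. A module is a list with class c("nn_<type>",
# "nn_module"). nnForward() returns list(out, cache, mod) -- `mod` carries
# updated buffers (batch-norm running statistics). nnBackward() returns
# list(dx, grads) with `grads` shaped exactly like the module's `params`.
# Feature maps are (H, W, C, N) arrays; vector features are N x d matrices.
# ---------------------------------------------------------------------------

nnModule <- function(type, ...) {
  structure(list(...), class = c(paste0("nn_", type), "nn_module"))
}

# He-normal initialisation for conv / linear weights; draws from the current RNG.
heNormal <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dim = dims)
}

nnConv <- function(inC, outC, k, stride = 1L, pad = 0L, bias = FALSE) {
  w <- heNormal(c(k, k, inC, outC), fanIn = k * k * inC)
  params <- list(w = w)
  if (bias) params$b <- numeric(outC)
  nnModule("conv", params = params, stride = as.integer(stride),
           pad = as.integer(pad), bias = bias)
}

nnBN <- function(C, numSplits = 1L, momentum = 0.1, eps = 1e-5) {
  nnModule("bn",
           params = list(gamma = rep(1, C), beta = rep(0, C)),
           runningMean = rep(0, C), runningVar = rep(1, C),
           numSplits = as.integer(numSplits), momentum = momentum, eps = eps)
}

nnReLU <- function() nnModule("relu", params = list())

nnMaxPool <- function(k = 3L, stride = 2L, pad = 1L) {
  nnModule("maxpool", params = list(), k = as.integer(k),
           stride = as.integer(stride), pad = as.integer(pad))
}

nnGlobalAvgPool <- function() nnModule("gap", params = list())

nnLinear <- function(inD, outD, bias = TRUE) {
  w <- matrix(stats::rnorm(outD * inD, sd = sqrt(2 / inD)), outD, inD)
  params <- list(w = w)
  if (bias) params$b <- numeric(outD)
  nnModule("linear", params = params, bias = bias)
}

nnL2Norm <- function(eps = 1e-12) nnModule("l2norm", params = list(), eps = eps)

nnSeq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  nnModule("seq", children = mods)
}

# Residual block: out = relu(main(x) + shortcut(x)); shortcut NULL = identity.
nnResidual <- function(main, shortcut = NULL) {
  nnModule("residual", main = main, shortcut = shortcut)
}

isComposite <- function(mod) !is.null(mod$children) || !is.null(mod$main)

# --- forward ----------------------------------------------------------------

nnForward <- function(mod, x, training = FALSE) {
  UseMethod("nnForward")
}

#' @export
nnForward.nn_conv <- function(mod, x, training = FALSE) {
  b <- if (mod$bias) mod$params$b else NULL
  y <- conv2d_fwd(x, mod$params$w, b, mod$stride, mod$pad)
  list(out = y, cache = list(x = x), mod = mod)
}

#' @export
nnForward.nn_bn <- function(mod, x, training = FALSE) {
  res <- splitBatchNormForward(x, mod$params$gamma, mod$params$beta,
                               numSplits = if (training) mod$numSplits else 1L,
                               training = training,
                               runningMean = mod$runningMean,
                               runningVar = mod$runningVar,
                               momentum = mod$momentum, eps = mod$eps)
  if (training) {
    mod$runningMean <- res$runningMean
    mod$runningVar <- res$runningVar
  }
  list(out = res$out, cache = res$cache, mod = mod)
}

#' @export
nnForward.nn_relu <- function(mod, x, training = FALSE) {
  mask <- x > 0
  list(out = x * mask, cache = list(mask = mask), mod = mod)
}

#' @export
nnForward.nn_maxpool <- function(mod, x, training = FALSE) {
  r <- maxpool_fwd(x, mod$k, mod$stride, mod$pad)
  list(out = r$y, cache = list(idx = r$idx, xdim = dim(x)), mod = mod)
}

#' @export
nnForward.nn_gap <- function(mod, x, training = FALSE) {
  d <- dim(x)
  m <- colMeans(array(x, c(d[1] * d[2], d[3] * d[4]))) # (C*N) means
  out <- t(matrix(m, d[3], d[4]))                      # N x C
  list(out = out, cache = list(xdim = d), mod = mod)
}

#' @export
nnForward.nn_linear <- function(mod, x, training = FALSE) {
  out <- x %*% t(mod$params$w)
  if (mod$bias) out <- sweep(out, 2, mod$params$b, "+")
  list(out = out, cache = list(x = x), mod = mod)
}

#' @export
nnForward.nn_l2norm <- function(mod, x, training = FALSE) {
  nrm <- sqrt(pmax(rowSums(x^2), mod$eps))
  out <- x / nrm
  list(out = out, cache = list(out = out, nrm = nrm), mod = mod)
}

#' @export
nnForward.nn_seq <- function(mod, x, training = FALSE) {
  caches <- vector("list", length(mod$children))
  for (i in seq_along(mod$children)) {
    r <- nnForward(mod$children[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    mod$children[[i]] <- r$mod
  }
  list(out = x, cache = caches, mod = mod)
}

#' @export
nnForward.nn_residual <- function(mod, x, training = FALSE) {
  rm_ <- nnForward(mod$main, x, training)
  mod$main <- rm_$mod
  if (is.null(mod$shortcut)) {
    s <- x
    cs <- NULL
  } else {
    rs <- nnForward(mod$shortcut, x, training)
    s <- rs$out
    cs <- rs$cache
    mod$shortcut <- rs$mod
  }
  pre <- rm_$out + s
  mask <- pre > 0
  list(out = pre * mask,
       cache = list(main = rm_$cache, shortcut = cs, mask = mask),
       mod = mod)
}

# --- backward ---------------------------------------------------------------

nnBackward <- function(mod, cache, dout) UseMethod("nnBackward")

#' @export
nnBackward.nn_conv <- function(mod, cache, dout) {
  g <- conv2d_bwd(cache$x, mod$params$w, dout, mod$stride, mod$pad, mod$bias)
  grads <- list(w = g$dw)
  if (mod$bias) grads$b <- g$db
  list(dx = g$dx, grads = grads)
}

#' @export
nnBackward.nn_bn <- function(mod, cache, dout) {
  g <- splitBatchNormBackward(cache, dout)
  list(dx = g$dx, grads = list(gamma = g$dgamma, beta = g$dbeta))
}

#' @export
nnBackward.nn_relu <- function(mod, cache, dout) {
  list(dx = dout * cache$mask, grads = list())
}

#' @export
nnBackward.nn_maxpool <- function(mod, cache, dout) {
  list(dx = maxpool_bwd(cache$idx, dout, cache$xdim), grads = list())
}

#' @export
nnBackward.nn_gap <- function(mod, cache, dout) {
  d <- cache$xdim
  # dout is N x C; broadcast /HW over spatial positions
  dx <- array(rep(as.vector(t(dout)) / (d[1] * d[2]), each = d[1] * d[2]),
              dim = d)
  list(dx = dx, grads = list())
}

#' @export
nnBackward.nn_linear <- function(mod, cache, dout) {
  grads <- list(w = t(dout) %*% cache$x)
  if (mod$bias) grads$b <- colSums(dout)
  list(dx = dout %*% mod$params$w, grads = grads)
}

#' @export
nnBackward.nn_l2norm <- function(mod, cache, dout) {
  proj <- rowSums(dout * cache$out)
  list(dx = (dout - cache$out * proj) / cache$nrm, grads = list())
}

#' @export
nnBackward.nn_seq <- function(mod, cache, dout) {
  n <- length(mod$children)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    r <- nnBackward(mod$children[[i]], cache[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

#' @export
nnBackward.nn_residual <- function(mod, cache, dout) {
  dpre <- dout * cache$mask
  rmain <- nnBackward(mod$main, cache$main, dpre)
  if (is.null(mod$shortcut)) {
    dx <- rmain$dx + dpre
    gshort <- NULL
  } else {
    rshort <- nnBackward(mod$shortcut, cache$shortcut, dpre)
    dx <- rmain$dx + rshort$dx
    gshort <- rshort$grads
  }
  list(dx = dx, grads = list(main = rmain$grads, shortcut = gshort))
}

# --- parameter tree walkers -------------------------------------------------

# Flat named list of all learnable parameters; names are slash paths.
nnParams <- function(mod, prefix = "") {
  out <- list()
  if (!is.null(mod$children)) {
    for (i in seq_along(mod$children))
      out <- c(out, nnParams(mod$children[[i]], paste0(prefix, i, "/")))
  } else if (!is.null(mod$main)) {
    out <- c(out, nnParams(mod$main, paste0(prefix, "main/")))
    if (!is.null(mod$shortcut))
      out <- c(out, nnParams(mod$shortcut, paste0(prefix, "shortcut/")))
  } else if (length(mod$params)) {
    for (nm in names(mod$params)) out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  }
  out
}

nnSetParams <- function(mod, flat, prefix = "") {
  if (!is.null(mod$children)) {
    for (i in seq_along(mod$children))
      mod$children[[i]] <- nnSetParams(mod$children[[i]], flat,
                                       paste0(prefix, i, "/"))
  } else if (!is.null(mod$main)) {
    mod$main <- nnSetParams(mod$main, flat, paste0(prefix, "main/"))
    if (!is.null(mod$shortcut))
      mod$shortcut <- nnSetParams(mod$shortcut, flat,
                                  paste0(prefix, "shortcut/"))
  } else if (length(mod$params)) {
    for (nm in names(mod$params)) {
      key <- paste0(prefix, nm)
      if (!is.null(flat[[key]])) mod$params[[nm]] <- flat[[key]]
    }
  }
  mod
}

# Flatten a grads tree (as returned by nnBackward) with the same path names.
nnFlattenGrads <- function(mod, grads, prefix = "") {
  out <- list()
  if (!is.null(mod$children)) {
    for (i in seq_along(mod$children))
      out <- c(out, nnFlattenGrads(mod$children[[i]], grads[[i]],
                                   paste0(prefix, i, "/")))
  } else if (!is.null(mod$main)) {
    out <- c(out, nnFlattenGrads(mod$main, grads$main, paste0(prefix, "main/")))
    if (!is.null(mod$shortcut))
      out <- c(out, nnFlattenGrads(mod$shortcut, grads$shortcut,
                                   paste0(prefix, "shortcut/")))
  } else if (length(mod$params)) {
    for (nm in names(mod$params)) out[[paste0(prefix, nm)]] <- grads[[nm]]
  }
  out
}
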