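#' Encoder architecture configuration
#'
#' Describes a residual-network image encoder. With \code{cifarRecipe} the
#' stem convolution is 3x3 stride 1 and the stem max-pooling layer is
#' removed (the small-image recipe); otherwise the stem is the standard
#' 7x7/stride-2 convolution followed by 3x3/stride-2 max pooling. Every
#' batch-normalization layer is a split variant with \code{numBnSplits}
#' groups (\code{numBnSplits = 1} reduces to standard batch normalization).
#' The final fully connected layer maps the pooled backbone width to
#' \code{featureDim}; outputs are L2-normalized rows when
#' \code{l2NormalizeOutput}.
#'
#' @param arch One of "resnet18", "resnet34", "resnet50", "resnet8" (a small
#'   three-stage residual net for desk-scale experiments).
#' @param featureDim Output feature length (default 128).
#' @param numBnSplits Batch-norm splits (default 8); must divide the
#'   training batch size.
#' @param cifarRecipe Use the small-image stem (default TRUE for
#'   resnet8/18/34, FALSE for resnet50).
#' @param l2NormalizeOutput Unit-normalize output rows (default TRUE).
#' @param simclrStem Replace the first convolution by kernel 3, stride 1,
#'   no padding while keeping the stem pooling (the SimCLR first-conv
#'   modification; default FALSE).
#' @param pretrained Request pretrained backbone weights. No offline weight
#'   source ships with the package, so TRUE raises an error at build time.
#' @return A validated list of class "encoderConfig".
#' @export
encoderConfig <- function(arch = c("resnet18", "resnet34", "resnet50",
                                   "resnet8"),
                          featureDim = 128L, numBnSplits = 8L,
                          cifarRecipe = NULL, l2NormalizeOutput = TRUE,
                          simclrStem = FALSE, pretrained = FALSE) {
  arch <- match.arg(arch)
  if (is.null(cifarRecipe)) cifarRecipe <- arch != "resnet50"
  if (simclrStem) cifarRecipe <- FALSE
  stopifnot(featureDim >= 1, numBnSplits >= 1)
  structure(list(arch = arch, featureDim = as.integer(featureDim),
                 numBnSplits = as.integer(numBnSplits),
                 cifarRecipe = cifarRecipe,
                 l2NormalizeOutput = l2NormalizeOutput,
                 simclrStem = simclrStem, pretrained = pretrained),
            class = "encoderConfig")
}

archSpec <- function(arch) {
  switch(arch,
    resnet8 = list(block = "basic", stem = 16L, widths = c(16L, 32L, 64L),
                   blocks = c(1L, 1L, 1L), backboneDim = 64L),
    resnet18 = list(block = "basic", stem = 64L,
                    widths = c(64L, 128L, 256L, 512L),
                    blocks = c(2L, 2L, 2L, 2L), backboneDim = 512L),
    resnet34 = list(block = "basic", stem = 64L,
                    widths = c(64L, 128L, 256L, 512L),
                    blocks = c(3L, 4L, 6L, 3L), backboneDim = 512L),
    resnet50 = list(block = "bottleneck", stem = 64L,
                    widths = c(64L, 128L, 256L, 512L),
                    blocks = c(3L, 4L, 6L, 3L), backboneDim = 2048L),
    stop("unknown arch: ", arch))
}

basicBlock <- function(inC, outC, stride, splits) {
  main <- nnSeq(list(
    nnConv(inC, outC, 3L, stride, 1L),
    nnBN(outC, splits),
    nnReLU(),
    nnConv(outC, outC, 3L, 1L, 1L),
    nnBN(outC, splits)))
  shortcut <- if (stride != 1L || inC != outC)
    nnSeq(list(nnConv(inC, outC, 1L, stride, 0L), nnBN(outC, splits)))
  nnResidual(main, shortcut)
}

bottleneckBlock <- function(inC, midC, stride, splits) {
  outC <- 4L * midC
  main <- nnSeq(list(
    nnConv(inC, midC, 1L, 1L, 0L),
    nnBN(midC, splits),
    nnReLU(),
    nnConv(midC, midC, 3L, stride, 1L),
    nnBN(midC, splits),
    nnReLU(),
    nnConv(midC, outC, 1L, 1L, 0L),
    nnBN(outC, splits)))
  shortcut <- if (stride != 1L || inC != outC)
    nnSeq(list(nnConv(inC, outC, 1L, stride, 0L), nnBN(outC, splits)))
  nnResidual(main, shortcut)
}

#' Build a residual-network encoder
#'
#' Constructs the network described by an \code{\link{encoderConfig}} with
#' He-normal weight initialization drawn from the current RNG (seed it with
#' \code{set.seed} or the \code{seed} argument for reproducible builds).
#'
#' @param config An \code{\link{encoderConfig}}.
#' @param seed Optional integer seed for the weight initialization.
#' @return An \code{\linkS4class{Encoder}}.
#' @examples
#' enc <- buildEncoder(encoderConfig("resnet8", featureDim = 16,
#'                                   numBnSplits = 2), seed = 1)
#' enc
#' @export
buildEncoder <- function(config, seed = NULL) {
  stopifnot(inherits(config, "encoderConfig"))
  if (isTRUE(config$pretrained))
    stop("pretrained backbone weights are not available in this package; ",
         "use pretrained = FALSE (random initialization)")
  spec <- archSpec(config$arch)
  splits <- config$numBnSplits
  withSeed(seed, {
    layers <- list()
    if (config$simclrStem) {
      layers <- c(layers, list(nnConv(3L, spec$stem, 3L, 1L, 0L),
                               nnBN(spec$stem, splits), nnReLU(),
                               nnMaxPool(3L, 2L, 1L)))
    } else if (config$cifarRecipe) {
      layers <- c(layers, list(nnConv(3L, spec$stem, 3L, 1L, 1L),
                               nnBN(spec$stem, splits), nnReLU()))
    } else {
      layers <- c(layers, list(nnConv(3L, spec$stem, 7L, 2L, 3L),
                               nnBN(spec$stem, splits), nnReLU(),
                               nnMaxPool(3L, 2L, 1L)))
    }
    inC <- spec$stem
    for (s in seq_along(spec$widths)) {
      width <- spec$widths[s]
      for (b in seq_len(spec$blocks[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        if (spec$block == "basic") {
          layers <- c(layers, list(basicBlock(inC, width, stride, splits)))
          inC <- width
        } else {
          layers <- c(layers, list(bottleneckBlock(inC, width, stride,
                                                   splits)))
          inC <- 4L * width
        }
      }
    }
    layers <- c(layers, list(nnGlobalAvgPool(),
                             nnLinear(spec$backboneDim, config$featureDim)))
    if (config$l2NormalizeOutput) layers <- c(layers, list(nnL2Norm()))
    methods::new("Encoder", net = nnSeq(layers), config = unclass(config))
  })
}

#' Forward an image batch through an encoder
#'
#' @param encoder An \code{\linkS4class{Encoder}}.
#' @param x Image batch array (H, W, 3, N).
#' @param training Use batch statistics and record caches (TRUE) or running
#'   statistics (FALSE, default).
#' @return list(features = N x featureDim matrix, encoder = encoder with
#'   updated running statistics, cache = backward-pass cache when training).
#' @export
encoderForward <- function(encoder, x, training = FALSE) {
  r <- nnForward(encoder@net, x, training)
  encoder@net <- r$mod
  list(features = r$out, encoder = encoder,
       cache = if (training) r$cache else NULL)
}

# Eval-mode features for dataset indices, batched.
encodeImages <- function(encoder, dataset, indices, size, batchSize = 64L,
                         mean = imagenetMean(), std = imagenetStd()) {
  out <- matrix(0, length(indices), encoder@config$featureDim)
  i <- 1L
  while (i <= length(indices)) {
    j <- min(i + batchSize - 1L, length(indices))
    xb <- makeEvalBatch(dataset, indices[i:j], size, mean, std)
    out[i:j, ] <- encoderForward(encoder, xb, training = FALSE)$features
    i <- j + 1L
  }
  out
}

#' Build a two-layer projection head
#'
#' A multilayer perceptron linear(inDim -> hidden) -> ReLU ->
#' linear(hidden -> outDim), as used on top of the SimCLR encoder.
#'
#' @param inDim Input width (default 2048).
#' @param hidden Hidden width (default 2048).
#' @param outDim Output width (default 128).
#' @param seed Optional seed for initialization.
#' @return A module usable with \code{\link{forwardModule}}.
#' @export
buildProjectionHead <- function(inDim = 2048L, hidden = 2048L,
                                outDim = 128L, seed = NULL) {
  stopifnot(inDim >= 1, hidden >= 1, outDim >= 1)
  withSeed(seed, nnSeq(list(nnLinear(inDim, hidden), nnReLU(),
                            nnLinear(hidden, outDim))))
}

#' Forward pass through a bare module
#'
#' Low-level helper exposing the layer framework's forward pass for modules
#' such as \code{\link{buildProjectionHead}} outputs; evaluation semantics
#' unless \code{training = TRUE}.
#'
#' @param module A layer module.
#' @param x Input (matrix or 4-d array, layer-dependent).
#' @param training Logical.
#' @return The module output.
#' @export
forwardModule <- function(module, x, training = FALSE) {
  nnForward(module, x, training)$out
}

#' Stem introspection of an encoder
#'
#' Reports the first-convolution kernel size and stride and whether a stem
#' max-pooling layer is present, for verifying the small-image recipe.
#'
#' @param encoder An \code{\linkS4class{Encoder}}.
#' @return list(kernel, stride, pad, hasStemPool).
#' @export
encoderStemInfo <- function(encoder) {
  ch <- encoder@net$children
  conv <- ch[[1]]
  stopifnot(inherits(conv, "nn_conv"))
  hasPool <- any(vapply(ch[1:min(4, length(ch))],
                        function(m) inherits(m, "nn_maxpool"), logical(1)))
  list(kernel = dim(conv$params$w)[1], stride = conv$stride,
       pad = conv$pad, hasStemPool = hasPool)
}
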