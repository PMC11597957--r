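#' @import methods
NULL

#' Labeled image dataset with a train/test split
#'
#' An ordered collection of (image, class label) records, labeled by class
#' index (0-based) and class name, together with a per-record train/test
#' split flag. Images may be held in memory (decoded H x W x 3 arrays) or
#' referenced by file path and decoded lazily.
#'
#' @slot images List of decoded images (H x W x 3 arrays in [0,1]) or NULLs
#'   for records loaded lazily from \code{paths}.
#' @slot paths Character vector of image file paths ("" when in-memory only).
#' @slot labels Integer vector of 0-based class indices.
#' @slot classNames Character vector of class names, ordered by class index.
#' @slot split Character vector, "train" or "test" per record.
#' @export
setClass("LabeledImageSet",
         representation(images = "list", paths = "character",
                        labels = "integer", classNames = "character",
                        split = "character"),
         validity = function(object) {
           n <- length(object@labels)
           if (length(object@images) != n || length(object@paths) != n ||
               length(object@split) != n)
             return("images, paths, labels and split must have equal length")
           k <- length(object@classNames)
           if (k < 1) return("classNames must be non-empty")
           if (n > 0 && (min(object@labels) < 0 || max(object@labels) >= k))
             return("labels must lie in [0, nClasses)")
           if (!all(object@split %in% c("train", "test")))
             return("split flags must be 'train' or 'test'")
           if (n > 0 && length(unique(object@labels)) < k)
             return("every class must have at least one record")
           TRUE
         })

#' Convolutional image encoder
#'
#' A configurable convolutional backbone mapping an image batch
#' (H, W, 3, N) to an N x featureDim matrix of (optionally unit-norm)
#' feature vectors. The layer stack and learnable parameters live in the
#' \code{net} slot; \code{config} records the architecture choices.
#'
#' @slot net Layer tree (internal representation).
#' @slot config The \code{\link{encoderConfig}} used to build the network.
#' @export
setClass("Encoder", representation(net = "ANY", config = "list"))

#' Momentum-contrast training state
#'
#' Holds the query encoder, the momentum (key) encoder, the FIFO queue of
#' negative key features, the ring-buffer write pointer (0-based), the EMA
#' momentum and the softmax temperature.
#'
#' @slot queryEncoder,keyEncoder \code{\linkS4class{Encoder}} objects with
#'   identical architectures.
#' @slot queue queueSize x featureDim matrix of unit-norm feature rows.
#' @slot queuePtr Integer in [0, queueSize), next write position.
#' @slot momentum EMA coefficient m in [0, 1].
#' @slot temperature Softmax temperature, > 0.
#' @export
setClass("MoCoState",
         representation(queryEncoder = "Encoder", keyEncoder = "Encoder",
                        queue = "matrix", queuePtr = "integer",
                        momentum = "numeric", temperature = "numeric"),
         validity = function(object) {
           K <- nrow(object@queue)
           if (K > 0) {
             nrm <- sqrt(rowSums(object@queue^2))
             if (any(abs(nrm - 1) > 1e-5))
               return("queue rows must be unit-norm (within 1e-5)")
           }
           if (object@queuePtr < 0 || (K > 0 && object@queuePtr >= K))
             return("queuePtr must lie in [0, queueSize)")
           if (object@momentum < 0 || object@momentum > 1)
             return("momentum must lie in [0, 1]")
           if (object@temperature <= 0)
             return("temperature must be positive")
           TRUE
         })

#' Memory bank of labeled feature vectors
#'
#' Unit-norm feature rows with class labels, the reference set for the
#' K-nearest-neighbour monitor classifier.
#'
#' @slot features N x d matrix with unit-norm rows.
#' @slot labels Integer vector of 0-based class indices, length N.
#' @slot numClasses Number of classes.
#' @export
setClass("MemoryBank",
         representation(features = "matrix", labels = "integer",
                        numClasses = "integer"),
         validity = function(object) {
           if (nrow(object@features) != length(object@labels))
             return("features and labels must have matching length")
           if (nrow(object@features) > 0) {
             nrm <- sqrt(rowSums(object@features^2))
             if (any(abs(nrm - 1) > 1e-5))
               return("feature rows must be unit-norm (within 1e-5)")
             if (min(object@labels) < 0 ||
                 max(object@labels) >= object@numClasses)
               return("labels must lie in [0, numClasses)")
           }
           TRUE
         })

#' Per-class classification report
#'
#' Per-class precision, recall, F1 and support, plus overall accuracy and
#' macro averages, in the layout of a standard multi-class classification
#' report.
#'
#' @slot perClass data.frame with columns class, precision, recall, f1,
#'   support.
#' @slot accuracy Overall accuracy in percent.
#' @slot macroPrecision,macroRecall,macroF1 Macro-averaged metrics (0-1).
#' @export
setClass("ClassificationReport",
         representation(perClass = "data.frame", accuracy = "numeric",
                        macroPrecision = "numeric", macroRecall = "numeric",
                        macroF1 = "numeric"))

# --- generics and accessors -------------------------------------------------

#' @describeIn LabeledImageSet Number of records.
#' @param object,x A LabeledImageSet.
#' @export
setMethod("length", "LabeledImageSet", function(x) length(x@labels))

#' Class names of a dataset or report
#' @param x Object with class labels.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname classNames
#' @export
setMethod("classNames", "LabeledImageSet", function(x) x@classNames)

#' Number of classes
#' @param x Object with class labels.
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname nClasses
#' @export
setMethod("nClasses", "LabeledImageSet", function(x) length(x@classNames))

#' Indices of the training split
#' @param x A LabeledImageSet.
#' @export
setGeneric("trainIndices", function(x) standardGeneric("trainIndices"))

#' @rdname trainIndices
#' @export
setMethod("trainIndices", "LabeledImageSet",
          function(x) which(x@split == "train"))

#' Indices of the test split
#' @param x A LabeledImageSet.
#' @export
setGeneric("testIndices", function(x) standardGeneric("testIndices"))

#' @rdname testIndices
#' @export
setMethod("testIndices", "LabeledImageSet",
          function(x) which(x@split == "test"))

#' Record labels (0-based class indices)
#' @param x A LabeledImageSet.
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @rdname imageLabels
#' @export
setMethod("imageLabels", "LabeledImageSet", function(x) x@labels)

#' Fetch one decoded image from a dataset
#'
#' @param x A LabeledImageSet.
#' @param i Record index (1-based).
#' @return An H x W x 3 array in [0, 1].
#' @export
setGeneric("getImage", function(x, i) standardGeneric("getImage"))

#' @rdname getImage
#' @export
setMethod("getImage", "LabeledImageSet", function(x, i) {
  img <- x@images[[i]]
  if (is.null(img)) img <- readImageFile(x@paths[i])
  img
})

#' Total parameter count of an encoder
#' @param object An Encoder.
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname nParameters
#' @export
setMethod("nParameters", "Encoder", function(object) {
  sum(vapply(nnParams(object@net), length, integer(1)))
})

setMethod("show", "LabeledImageSet", function(object) {
  cat("LabeledImageSet with", length(object@labels), "records,",
      length(object@classNames), "classes\n")
  cat("  classes:", paste(object@classNames, collapse = ", "), "\n")
  cat("  split:", sum(object@split == "train"), "train /",
      sum(object@split == "test"), "test\n")
})

setMethod("show", "Encoder", function(object) {
  cat("Encoder:", object@config$arch,
      if (isTRUE(object@config$cifarRecipe)) "(CIFAR recipe)" else "",
      "\n")
  cat("  feature dim:", object@config$featureDim,
      "| BN splits:", object@config$numBnSplits,
      "| parameters:", format(nParameters(object), big.mark = ","), "\n")
})

setMethod("show", "MoCoState", function(object) {
  cat("MoCoState: queue", nrow(object@queue), "x", ncol(object@queue),
      "| ptr", object@queuePtr, "| m =", object@momentum,
      "| tau =", object@temperature, "\n")
})

setMethod("show", "MemoryBank", function(object) {
  cat("MemoryBank:", nrow(object@features), "features x",
      ncol(object@features), "dims,", object@numClasses, "classes\n")
})

setMethod("show", "ClassificationReport", function(object) {
  df <- object@perClass
  df$precision <- sprintf("%.4f", df$precision)
  df$recall <- sprintf("%.4f", df$recall)
  df$f1 <- sprintf("%.4f", df$f1)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy: %.2f%%\n", object@accuracy))
  cat(sprintf("macro avg: precision %.4f  recall %.4f  f1 %.4f\n",
              object@macroPrecision, object@macroRecall, object@macroF1))
})
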