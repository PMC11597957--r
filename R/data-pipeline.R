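#' Two-view contrastive augmentation configuration
#'
#' The augmentation recipe applied independently twice to each training image
#' to form a positive pair: random resized crop, random horizontal flip,
#' random color jitter, then per-channel normalization (applied exactly once,
#' last).
#'
#' @param cropSize Output side in pixels.
#' @param cropScale Length-2 numeric, (min, max) area fraction sampled by the
#'   random resized crop (default c(0.2, 1)).
#' @param pHflip Horizontal-flip probability (default 0.5).
#' @param jitter Length-4 numeric: brightness, contrast, saturation, hue
#'   jitter magnitudes (default c(0.4, 0.4, 0.4, 0.1)).
#' @param pJitter Probability of applying the color jitter (default 0.8).
#' @param mean,std Per-channel normalization statistics (ImageNet defaults).
#' @return A validated list of class "augmentationConfig".
#' @export
augmentationConfig <- function(cropSize, cropScale = c(0.2, 1),
                               pHflip = 0.5,
                               jitter = c(0.4, 0.4, 0.4, 0.1),
                               pJitter = 0.8,
                               mean = imagenetMean(), std = imagenetStd()) {
  stopifnot(cropSize >= 1, length(cropScale) == 2, cropScale[1] > 0,
            cropScale[2] <= 1, cropScale[1] <= cropScale[2],
            pHflip >= 0, pHflip <= 1, length(jitter) == 4, all(jitter >= 0),
            pJitter >= 0, pJitter <= 1, length(mean) == 3, length(std) == 3)
  structure(list(cropSize = as.integer(cropSize), cropScale = cropScale,
                 pHflip = pHflip, jitter = jitter, pJitter = pJitter,
                 mean = mean, std = std),
            class = "augmentationConfig")
}

#' Load a class-per-folder image dataset
#'
#' Reads a directory tree with one subdirectory per class (PNG/JPEG images),
#' labels records by folder name (sorted lexicographically, 0-based class
#' indices) and assigns a seeded stratified train/test split: per class,
#' \code{round(testFraction * n)} images (at least 1 when the class has more
#' than one image) go to the test split. Undecodable files are skipped with
#' a warning. The split is deterministic in \code{seed}.
#'
#' @param rootDir Directory containing >= 2 class subdirectories.
#' @param testFraction Test fraction in (0, 1) (default 0.2).
#' @param seed Integer seed for the split.
#' @param keepInMemory Decode all images now (TRUE, default) or lazily.
#' @return A \code{\linkS4class{LabeledImageSet}}.
#' @export
loadImageDataset <- function(rootDir, testFraction = 0.2, seed = 42L,
                             keepInMemory = TRUE) {
  if (!dir.exists(rootDir)) stop("directory does not exist: ", rootDir)
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  dirs <- sort(list.dirs(rootDir, recursive = FALSE, full.names = TRUE))
  if (length(dirs) < 2) stop("need at least 2 class subdirectories")
  classNames <- basename(dirs)

  paths <- character(0)
  labels <- integer(0)
  for (ci in seq_along(dirs)) {
    fs <- sort(list.files(dirs[ci], full.names = TRUE,
                          pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                          ignore.case = TRUE))
    if (length(fs) == 0) stop("class folder has no images: ", dirs[ci])
    paths <- c(paths, fs)
    labels <- c(labels, rep(ci - 1L, length(fs)))
  }

  images <- vector("list", length(paths))
  ok <- rep(TRUE, length(paths))
  if (keepInMemory) {
    for (i in seq_along(paths)) {
      img <- tryCatch(readImageFile(paths[i]), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping undecodable image: ", paths[i])
        ok[i] <- FALSE
      } else {
        images[[i]] <- img
      }
    }
  }
  paths <- paths[ok]
  labels <- labels[ok]
  images <- images[ok]
  if (any(!(seq_along(classNames) - 1L) %in% labels))
    stop("a class folder has no decodable images")

  split <- character(length(labels))
  withSeed(seed, {
    for (ci in seq_along(classNames) - 1L) {
      idx <- which(labels == ci)
      nTest <- round(testFraction * length(idx))
      if (nTest < 1L && length(idx) > 1L) nTest <- 1L
      if (nTest >= length(idx)) nTest <- length(idx) - 1L
      testIdx <- if (nTest > 0) sample(idx, nTest) else integer(0)
      split[idx] <- "train"
      split[testIdx] <- "test"
    }
  })

  methods::new("LabeledImageSet", images = images, paths = paths,
               labels = labels, classNames = classNames, split = split)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

# Random resized crop (area-scale + aspect-ratio sampling, 10 attempts,
# center-crop fallback), resized to size x size.
randomResizedCrop <- function(img, size, scale, ratio = c(3 / 4, 4 / 3)) {
  H <- dim(img)[1]
  W <- dim(img)[2]
  area <- H * W
  for (attempt in 1:10) {
    targetArea <- area * stats::runif(1, scale[1], scale[2])
    logR <- stats::runif(1, log(ratio[1]), log(ratio[2]))
    ar <- exp(logR)
    w <- round(sqrt(targetArea * ar))
    h <- round(sqrt(targetArea / ar))
    if (w >= 1 && h >= 1 && w <= W && h <= H) {
      top <- sample.int(H - h + 1L, 1L)
      left <- sample.int(W - w + 1L, 1L)
      crop <- img[top:(top + h - 1L), left:(left + w - 1L), , drop = FALSE]
      return(resizeBilinear(crop, size, size))
    }
  }
  side <- min(H, W)
  top <- (H - side) %/% 2 + 1L
  left <- (W - side) %/% 2 + 1L
  crop <- img[top:(top + side - 1L), left:(left + side - 1L), , drop = FALSE]
  resizeBilinear(crop, size, size)
}

# Color jitter in fixed order brightness -> contrast -> saturation -> hue,
# each factor sampled uniformly from its magnitude interval.
colorJitter <- function(img, jitter) {
  b <- jitter[1]; ct <- jitter[2]; sa <- jitter[3]; hu <- jitter[4]
  if (b > 0) img <- img * stats::runif(1, max(0, 1 - b), 1 + b)
  if (ct > 0) {
    f <- stats::runif(1, max(0, 1 - ct), 1 + ct)
    gray <- mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    img <- f * img + (1 - f) * gray
  }
  if (sa > 0) {
    f <- stats::runif(1, max(0, 1 - sa), 1 + sa)
    gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    for (ch in 1:3) img[, , ch] <- f * img[, , ch] + (1 - f) * gray
  }
  img <- pmin(pmax(img, 0), 1)
  if (hu > 0) {
    shift <- stats::runif(1, -hu, hu)
    hsv <- rgb2hsvArr(img)
    hsv[, , 1] <- (hsv[, , 1] + shift) %% 1
    img <- hsv2rgbArr(hsv)
  }
  pmin(pmax(img, 0), 1)
}

# One stochastic view: crop -> flip -> jitter -> normalize (exactly once).
augmentOnce <- function(img, config) {
  v <- randomResizedCrop(img, config$cropSize, config$cropScale)
  if (config$pHflip > 0 && stats::runif(1) < config$pHflip)
    v <- v[, dim(v)[2]:1, , drop = FALSE]
  if (config$pJitter > 0 && stats::runif(1) < config$pJitter)
    v <- colorJitter(v, config$jitter)
  normalizeChannels(v, config$mean, config$std)
}

#' Augment one image into two contrastive views
#'
#' Applies the augmentation pipeline of \code{\link{augmentationConfig}}
#' twice, with independent random draws, to the same source image. The two
#' returned views are the positive pair of contrastive training.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param config An \code{\link{augmentationConfig}}.
#' @param seed Optional integer; when given, the pair is a deterministic
#'   function of (image, config, seed).
#' @return list(viewA, viewB): normalized cropSize x cropSize x 3 arrays.
#' @export
twoViewAugment <- function(image, config, seed = NULL) {
  stopifnot(inherits(config, "augmentationConfig"))
  withSeed(seed, {
    list(viewA = augmentOnce(image, config),
         viewB = augmentOnce(image, config))
  })
}

#' Deterministic evaluation transform
#'
#' Resizes to size x size (bilinear) and normalizes per channel; no
#' randomness.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param size Output side in pixels.
#' @param mean,std Per-channel normalization statistics.
#' @return A size x size x 3 normalized array.
#' @export
evalTransform <- function(image, size, mean = imagenetMean(),
                          std = imagenetStd()) {
  normalizeChannels(resizeBilinear(image, size, size), mean, std)
}

# Build normalized two-view batch arrays (H, W, 3, B) for dataset indices.
makeTwoViewBatch <- function(dataset, indices, config) {
  a <- vector("list", length(indices))
  b <- vector("list", length(indices))
  for (j in seq_along(indices)) {
    img <- getImage(dataset, indices[j])
    pair <- twoViewAugment(img, config)
    a[[j]] <- pair$viewA
    b[[j]] <- pair$viewB
  }
  list(viewA = stackImages(a), viewB = stackImages(b), indices = indices)
}

# Eval-transformed batch array for dataset indices.
makeEvalBatch <- function(dataset, indices, size, mean = imagenetMean(),
                          std = imagenetStd()) {
  imgs <- lapply(indices, function(i)
    evalTransform(getImage(dataset, i), size, mean, std))
  stackImages(imgs)
}
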