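#' Configuration for the synthetic emotion-image generator
#'
#' Describes a balanced, class-per-folder synthetic image dataset standing in
#' for a withheld animal-emotion photograph collection. Each class is given a
#' distinct generative rule -- a "posture" ellipse with a class-specific
#' orientation, an "ear" triangle at a class-specific position on the body
#' outline, and a class hue band -- perturbed by nuisance background texture,
#' global brightness jitter and small geometric noise.
#'
#' @param nClasses Number of classes (>= 2, default 7).
#' @param nPerClass Images per class (default 300).
#' @param imageSize Square image side in pixels (>= 16, default 96).
#' @param signalStrength Real in [0, 1]: how salient the class-defining
#'   features are (1 = fully deterministic class geometry and hue).
#' @param nuisanceStrength Real in [0, 1]: amplitude of background texture,
#'   lighting jitter and geometric noise.
#' @param testFraction Fraction of each class assigned to the test split in
#'   the written manifest (default 0.2).
#' @param seed Integer RNG seed; the dataset is a pure function of the
#'   configuration.
#' @return A validated list of class "syntheticConfig".
#' @export
syntheticConfig <- function(nClasses = 7L, nPerClass = 300L, imageSize = 96L,
                            signalStrength = 0.8, nuisanceStrength = 0.3,
                            testFraction = 0.2, seed = 42L) {
  nClasses <- as.integer(nClasses)
  nPerClass <- as.integer(nPerClass)
  imageSize <- as.integer(imageSize)
  if (is.na(nClasses) || nClasses < 2L) stop("nClasses must be >= 2")
  if (nPerClass < 1L) stop("nPerClass must be positive")
  if (imageSize < 16L) stop("imageSize must be >= 16")
  if (signalStrength < 0 || signalStrength > 1)
    stop("signalStrength must lie in [0, 1]")
  if (nuisanceStrength < 0 || nuisanceStrength > 1)
    stop("nuisanceStrength must lie in [0, 1]")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  structure(list(nClasses = nClasses, nPerClass = nPerClass,
                 imageSize = imageSize, signalStrength = signalStrength,
                 nuisanceStrength = nuisanceStrength,
                 testFraction = testFraction, seed = as.integer(seed)),
            class = "syntheticConfig")
}

# The seven primal mammalian emotion labels used when nClasses == 7.
pankseppNames <- function() {
  c("Exploring", "Sadness", "Playing", "Rage", "Fear", "Affectionate", "Lust")
}

syntheticClassNames <- function(nClasses) {
  nm <- if (nClasses == 7L) pankseppNames()
        else paste0("class_", seq_len(nClasses) - 1L)
  sort(nm) # lexicographic order fixes the class-index convention
}

# Deterministic per-image seed below 2^31, mixing config seed, class, index.
imageSeed <- function(seed, classIdx, i) {
  as.integer((as.numeric(seed %% 100003L) * 10007 +
                classIdx * 97 + i * 13) %% 2147483647)
}

# Render one synthetic image for (0-based) class c of k. Uses the current RNG.
renderSyntheticImage <- function(c, k, s, signal, nuisance) {
  # nuisance background: warm-gray base plus coarse smooth texture
  base <- c(0.45, 0.42, 0.38)
  img <- array(rep(base, each = s * s), c(s, s, 3))
  if (nuisance > 0) {
    coarse <- array(stats::runif(4 * 4 * 3, -1, 1), c(4, 4, 3)) * 0.25 * nuisance
    img <- img + resizeBilinear(coarse, s, s)
    tint <- stats::runif(3, -1, 1) * 0.1 * nuisance
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tint[ch]
  }

  # class rule: orientation, ear position and hue are class functions,
  # diluted by (1 - signal) and jittered by nuisance
  thetaC <- pi * c / k
  theta <- thetaC + (1 - signal) * stats::runif(1, -pi / 2, pi / 2) +
    nuisance * stats::runif(1, -pi / 12, pi / 12)
  phiC <- 2 * pi * c / k
  phi <- phiC + (1 - signal) * stats::runif(1, -pi, pi) +
    nuisance * stats::runif(1, -pi / 18, pi / 18)
  hue <- c / k + (1 - signal) * stats::runif(1, -0.5, 0.5) +
    nuisance * stats::runif(1, -0.03, 0.03)

  cx <- 0.5 + nuisance * stats::runif(1, -0.06, 0.06)
  cy <- 0.5 + nuisance * stats::runif(1, -0.06, 0.06)
  a <- 0.32 * (1 + nuisance * stats::runif(1, -0.15, 0.15))
  b <- 0.16 * (1 + nuisance * stats::runif(1, -0.15, 0.15))

  xy <- (seq_len(s) - 0.5) / s
  X <- matrix(xy, s, s)            # rows vary
  Y <- matrix(xy, s, s, byrow = TRUE)
  dx <- X - cx
  dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  body <- (u / a)^2 + (v / b)^2 <= 1

  bodyCol <- hsv2rgbMat(hue, 0.75, 0.7)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[body] <- bodyCol[ch]
    img[, , ch] <- plane
  }

  # "ear" triangle attached at body-frame angle phi on the ellipse outline
  ex <- cx + a * cos(phi) * cos(theta) - b * sin(phi) * sin(theta)
  ey <- cy + a * cos(phi) * sin(theta) + b * sin(phi) * cos(theta)
  r <- 0.09
  ang <- atan2(ey - cy, ex - cx)
  p1 <- c(ex + r * cos(ang), ey + r * sin(ang))
  p2 <- c(ex + 0.5 * r * cos(ang + 2.5), ey + 0.5 * r * sin(ang + 2.5))
  p3 <- c(ex + 0.5 * r * cos(ang - 2.5), ey + 0.5 * r * sin(ang - 2.5))
  sgn <- function(px, py, qx, qy) (X - qx) * (py - qy) - (Y - qy) * (px - qx)
  d1 <- sgn(p1[1], p1[2], p2[1], p2[2])
  d2 <- sgn(p2[1], p2[2], p3[1], p3[2])
  d3 <- sgn(p3[1], p3[2], p1[1], p1[2])
  ear <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
  earCol <- hsv2rgbMat((hue + 0.5) %% 1, 0.8, 0.6)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ear] <- earCol[ch]
    img[, , ch] <- plane
  }

  # lighting: global brightness jitter
  if (nuisance > 0) img <- img * (1 + nuisance * stats::runif(1, -0.35, 0.35))
  pmin(pmax(img, 0), 1)
}

#' Generate a balanced synthetic emotion-image dataset
#'
#' Writes one subdirectory per class (the seven Panksepp emotion names when
#' \code{nClasses == 7}, otherwise \code{class_0 ... class_{k-1}}), each with
#' exactly \code{nPerClass} PNG images of size imageSize x imageSize x 3, a
#' manifest CSV (\code{path,class_index,class_name,split}), and returns the
#' dataset as a \code{\linkS4class{LabeledImageSet}} with the images held in
#' memory. Class indices follow the lexicographic order of the class names,
#' matching \code{\link{loadImageDataset}}. Fully reproducible: identical
#' configurations produce byte-identical PNG files.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @param outDir Output directory (created if missing). NULL keeps the
#'   dataset in memory only.
#' @return A \code{\linkS4class{LabeledImageSet}}.
#' @examples
#' cfg <- syntheticConfig(nClasses = 2, nPerClass = 2, imageSize = 16)
#' ds <- generateSyntheticEmotionDataset(cfg, outDir = NULL)
#' ds
#' @export
generateSyntheticEmotionDataset <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "syntheticConfig"))
  k <- config$nClasses
  classNames <- syntheticClassNames(k)
  writeOut <- !is.null(outDir)
  if (writeOut) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
  }

  n <- k * config$nPerClass
  images <- vector("list", n)
  paths <- character(n)
  labels <- integer(n)
  split <- character(n)

  # deterministic stratified split: the last ceil(testFraction * n) of each
  # class's seeded shuffle goes to test
  rec <- 0L
  for (ci in seq_len(k) - 1L) {
    nTest <- max(1L, round(config$testFraction * config$nPerClass))
    if (nTest >= config$nPerClass) nTest <- config$nPerClass - 1L
    set.seed(imageSeed(config$seed, ci, 0L))
    testIdx <- sample(config$nPerClass, nTest)
    if (writeOut)
      dir.create(file.path(outDir, classNames[ci + 1L]), showWarnings = FALSE)
    for (i in seq_len(config$nPerClass)) {
      rec <- rec + 1L
      set.seed(imageSeed(config$seed, ci, i))
      img <- renderSyntheticImage(ci, k, config$imageSize,
                                  config$signalStrength,
                                  config$nuisanceStrength)
      images[[rec]] <- img
      labels[rec] <- ci
      split[rec] <- if (i %in% testIdx) "test" else "train"
      if (writeOut) {
        p <- file.path(outDir, classNames[ci + 1L],
                       sprintf("img_%04d.png", i))
        writeImagePNG(img, p)
        paths[rec] <- p
      }
    }
  }

  ds <- methods::new("LabeledImageSet", images = images, paths = paths,
                     labels = labels, classNames = classNames, split = split)
  if (writeOut) {
    manifest <- data.frame(path = paths, class_index = labels,
                           class_name = classNames[labels + 1L],
                           split = split)
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  ds
}

#' Chance accuracy of uniform guessing on balanced classes
#'
#' @param nClasses Number of equally frequent classes (>= 1).
#' @return The expected accuracy of uniform random guessing, in percent
#'   (100 / nClasses).
#' @examples
#' chanceAccuracy(7) # 14.2857...
#' chanceAccuracy(4) # 25
#' @export
chanceAccuracy <- function(nClasses) {
  if (length(nClasses) != 1L || is.na(nClasses) || nClasses < 1)
    stop("nClasses must be a positive integer")
  100 / nClasses
}
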