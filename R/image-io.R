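# Image handling. The package-wide pixel convention is a numeric H x W x 3
# array with values in [0, 1] (RGB). PNG goes through the png package for
# byte-exact round trips; JPEG/TIFF decode through EBImage.

readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores (x, y, c); transpose to (row, col, c)
    a <- if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  a
}

writeImagePNG <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, target = path)
  invisible(path)
}

# Bilinear resize of an H x W x 3 array (EBImage backend; its first axis is
# simply the first array axis, so no transposition is needed).
resizeBilinear <- function(img, outH, outW) {
  if (dim(img)[1] == outH && dim(img)[2] == outW) return(img)
  y <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                       w = outH, h = outW)
  a <- EBImage::imageData(y)
  dim(a) <- c(outH, outW, dim(img)[3])
  a
}

# Vectorized HSV -> RGB for h, s, v in [0, 1]; returns a 3-column matrix.
hsv2rgbMat <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t_ <- v * (1 - s * (1 - f))
  i <- i %% 6
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Vectorized RGB -> HSV on an H x W x 3 array; returns same-shape array.
rgb2hsvArr <- function(img) {
  d <- dim(img)
  m <- matrix(img, d[1] * d[2], 3)
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  array(hsv, d)
}

hsv2rgbArr <- function(hsv) {
  d <- dim(hsv)
  m <- matrix(hsv, d[1] * d[2], 3)
  array(hsv2rgbMat(m[, 1], m[, 2], m[, 3]), d)
}

# Per-channel standardization: (x - mean) / sd, applied channel-wise.
normalizeChannels <- function(img, mean, std) {
  for (c in 1:3) img[, , c] <- (img[, , c] - mean[c]) / std[c]
  img
}

imagenetMean <- function() c(0.485, 0.456, 0.406)
imagenetStd <- function() c(0.229, 0.224, 0.225)

# Stack a list of H x W x 3 images into an (H, W, 3, N) batch array.
stackImages <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}
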