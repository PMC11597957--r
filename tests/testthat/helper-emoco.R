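# Shared fixtures and independent oracles, all built in code at test time.

# Small in-memory synthetic dataset.
tinyDataset <- function(nClasses = 2L, nPerClass = 8L, size = 16L,
                        signal = 0.9, nuisance = 0.3, seed = 7L,
                        testFraction = 0.25) {
  generateSyntheticEmotionDataset(
    syntheticConfig(nClasses = nClasses, nPerClass = nPerClass,
                    imageSize = size, signalStrength = signal,
                    nuisanceStrength = nuisance,
                    testFraction = testFraction, seed = seed))
}

randUnitRows <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# Independent oracle: nearest-class-mean pixel classifier accuracy (percent)
# on the test split, using raw flattened images.
nearestClassMeanAccuracy <- function(ds) {
  tr <- trainIndices(ds)
  te <- testIndices(ds)
  labs <- imageLabels(ds)
  flat <- function(i) as.vector(getImage(ds, i))
  Xtr <- t(vapply(tr, flat, numeric(length(flat(tr[1])))))
  Xte <- t(vapply(te, flat, numeric(ncol(Xtr))))
  k <- nClasses(ds)
  centroids <- t(vapply(seq_len(k) - 1L,
                        function(c) colMeans(Xtr[labs[tr] == c, , drop = FALSE]),
                        numeric(ncol(Xtr))))
  pred <- apply(Xte, 1, function(x)
    which.min(colSums((t(centroids) - x)^2)) - 1L)
  100 * mean(pred == labs[te])
}

# Independent oracle: standard (single-group) batch normalization, training
# mode, written directly from the definition.
standardBNOracle <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  out <- array(0, d)
  for (c in seq_len(d[3])) {
    v <- x[, , c, , drop = FALSE]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    out[, , c, ] <- gamma[c] * (v - mu) / sqrt(va + eps) + beta[c]
  }
  out
}

# Independent oracle: brute-force temperature-weighted KNN prediction.
bruteForceKnn <- function(queries, bankF, bankL, k, temp, numClasses) {
  t(apply(queries, 1, function(q) {
    sim <- as.vector(bankF %*% q)
    ord <- order(-sim, seq_along(sim))[seq_len(min(k, length(sim)))]
    w <- exp(sim[ord] / temp)
    sc <- numeric(numClasses)
    for (j in seq_along(ord)) {
      cls <- bankL[ord[j]] + 1L
      sc[cls] <- sc[cls] + w[j]
    }
    c(which.max(sc) - 1L, sc / sum(sc))
  }))
}

# Independent oracle: (1 + K)-way softmax cross-entropy with target index 1.
softmaxCE0 <- function(logits) {
  -log(exp(logits[1]) / sum(exp(logits)))
}

# Cache for expensive shared computations within a test run.
.sharedRuns <- new.env(parent = emptyenv())
sharedRun <- function(key, expr) {
  if (is.null(.sharedRuns[[key]])) .sharedRuns[[key]] <- force(expr)
  .sharedRuns[[key]]
}
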