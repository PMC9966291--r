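# shared fixtures and independent oracles

# desk-scale scan settings used throughout the tests: the scanner's study
# conditions except for a coarser sampling resolution (see the vignette)
testScan <- function(seed = 1L, spacing = 0.35, noise = 0.02, ...) {
  scanSpec(pointSpacingMm = spacing, noiseSdMm = noise, seed = seed, ...)
}

# a single 20 x 20 mm square in the z = 0 plane
unitSquareMesh <- function(half = 10) {
  triangleMesh(rbind(c(-half, -half, 0), c(half, -half, 0),
                     c(half, half, 0), c(-half, half, 0)),
               rbind(c(1, 2, 3), c(1, 3, 4)), c("face", "face"))
}

# a deliberately asymmetric compact cloud (all axes skewed)
asymmetricCloud <- function(n = 400, seed = 3L) {
  set.seed(seed)
  p <- cbind(rexp(n, 1), 2 * rexp(n, 0.7), 0.5 * rexp(n, 2))
  pointCloud(p + matrix(rnorm(3 * n, 0, 0.01), n, 3))
}

# exhaustive O(n^2) nearest-neighbor scan (tie: lowest index)
bruteNearest <- function(query, reference) {
  Q <- if (is(query, "PointCloud")) coords(query) else query
  R <- if (is(reference, "PointCloud")) coords(reference) else reference
  idx <- integer(nrow(Q))
  d <- numeric(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    dd <- sqrt(colSums((t(R) - Q[i, ])^2))
    j <- which(dd == min(dd))[1]
    idx[i] <- j
    d[i] <- dd[j]
  }
  list(index = idx, distance = d)
}

# RMS of residuals from the best-fit plane of a point set
planeFitRms <- function(P) {
  P0 <- sweep(P, 2, colMeans(P))
  sqrt(min(svd(P0, nu = 0, nv = 0)$d^2) / nrow(P0))
}

randomCloud <- function(n, seed, scale = 10) {
  set.seed(seed)
  matrix(runif(3 * n, -scale, scale), n, 3)
}
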