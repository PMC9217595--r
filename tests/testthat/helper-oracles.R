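# Independent oracles used by the unit and acceptance tests.  Each one is a
# direct, slow re-derivation of the quantity it checks and never calls the
# implementation under test.

# Exhaustive nearest-p patch search: score every candidate patch in the
# clipped window by explicit pixel loops.
bruteForceBlockMatch <- function(px, refLoc, patchSize, searchWindow,
                                 groupSize) {
  h <- nrow(px); w <- ncol(px)
  half <- (searchWindow - patchSize) %/% 2
  rr <- refLoc[1]; rc <- refLoc[2]
  ref <- px[rr:(rr + patchSize - 1), rc:(rc + patchSize - 1)]
  cand <- expand.grid(
    row = max(1, rr - half):min(h - patchSize + 1, rr + half),
    col = max(1, rc - half):min(w - patchSize + 1, rc + half))
  cand <- cand[order(cand$row, cand$col), ]  # raster order
  d <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    patch <- px[cand$row[i]:(cand$row[i] + patchSize - 1),
                cand$col[i]:(cand$col[i] + patchSize - 1)]
    d[i] <- sum((patch - ref)^2)
  }
  notRef <- !(cand$row == rr & cand$col == rc)
  # reference outranks zero-distance ties; remaining ties in raster order
  ord <- order(d, notRef)[seq_len(min(groupSize, nrow(cand)))]
  cbind(row = cand$row[ord], col = cand$col[ord])
}

# Per-singular-value scalar objective of weighted nuclear norm shrinkage:
# 0.5 * (x - sv)^2 + w * x over x >= 0, minimised by two-stage grid
# refinement (coarse grid, then a fine grid inside the winning interval).
gridShrinkOracle <- function(sv, w, levels = 3L, pointsPerLevel = 2001L) {
  lo <- 0; hi <- max(sv, 1e-8)
  for (l in seq_len(levels)) {
    xs <- seq(lo, hi, length.out = pointsPerLevel)
    obj <- 0.5 * (xs - sv)^2 + w * xs
    i <- which.min(obj)
    lo <- xs[max(1L, i - 1L)]
    hi <- xs[min(pointsPerLevel, i + 1L)]
  }
  (lo + hi) / 2
}

# Full-matrix oracle: SVD the input, replace each singular value by the
# grid-search minimiser, reconstruct.
gridSVTOracle <- function(mat, weights) {
  sv <- svd(mat)
  k <- length(sv$d)
  shrunk <- vapply(seq_len(k),
                   function(t) gridShrinkOracle(sv$d[t], weights[t]), 0)
  sv$u %*% diag(shrunk, k) %*% t(sv$v)
}

# Mann-Whitney AUC by exhaustive pair enumeration with midrank ties.
aucByPairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Raw two-group samples with exactly the requested mean and sd.
samplesWithMoments <- function(m, s, n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  m + s * x
}

smallPhantom <- function(size = 32L, smoothSigma = 0) {
  generatePhantom(size, size,
                  blobs = rbind(
                    phantomBlob(0.4 * size, 0.4 * size, 0.22 * size,
                                0.15 * size, 0.4, 0.8),
                    phantomBlob(0.7 * size, 0.65 * size, 0.12 * size,
                                0.12 * size, 0, 0.6)),
                  smoothSigma = smoothSigma)
}
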