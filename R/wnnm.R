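#' Reference patch grid
#'
#' Top-left coordinates of reference patches on a regular grid of spacing
#' \code{step}; the last row and column are clamped to the image border so
#' that every pixel is covered by at least one reference patch when
#' \code{step <= patchSize}.
#'
#' @param dim integer vector (rows, cols) of the image, or a GrayImage.
#' @param patchSize patch side length.
#' @param step stride between reference patches.
#' @return Integer matrix with columns \code{row}, \code{col} (1-based).
#' @examples
#' referencePatchGrid(c(10, 10), patchSize = 4, step = 4)
#' @export
referencePatchGrid <- function(dim, patchSize, step) {
  if (is(dim, "GrayImage") || is.matrix(dim)) dim <- base::dim(asPixels(dim))
  h <- dim[1]; w <- dim[2]
  if (h < patchSize || w < patchSize)
    stop("image smaller than one patch")
  lastR <- h - patchSize + 1L
  lastC <- w - patchSize + 1L
  rows <- unique(c(seq.int(1L, lastR, by = step), lastR))
  cols <- unique(c(seq.int(1L, lastC, by = step), lastC))
  cbind(row = rep(rows, times = length(cols)),
        col = rep(cols, each = length(rows)))
}

# column-major linear offsets of the pixels of one patch anchored at (1,1)
patchOffsets <- function(patchSize, imageRows) {
  as.vector(outer(0:(patchSize - 1L), (0:(patchSize - 1L)) * imageRows, "+"))
}

#' Group similar patches by block matching
#'
#' Collects the \code{groupSize} patches closest (squared Euclidean distance)
#' to the reference patch among all patches whose support lies inside the
#' search window centred on the reference, clipped at the image borders.
#' Columns are ordered by ascending distance; the reference precedes any
#' other zero-distance patch (so it is always the first column), and
#' remaining ties break by raster (row-major) order of the candidate
#' location, so the result is fully deterministic.  If the window holds
#' fewer candidates than \code{groupSize}, all candidates are returned.
#'
#' @param image a \linkS4class{GrayImage} or numeric matrix.
#' @param refLocation integer (row, col) of the reference patch top-left.
#' @param params a \linkS4class{WNNMParams}.
#' @return A \linkS4class{PatchGroup}.
#' @examples
#' img <- generatePhantom(32, 32)
#' g <- blockMatch(img, c(5, 5), WNNMParams(patchSize = 4, groupSize = 10,
#'                                          searchWindow = 12))
#' referenceIndex(g)
#' @export
blockMatch <- function(image, refLocation, params) {
  px <- asPixels(image)
  h <- nrow(px); w <- ncol(px)
  ps <- params@patchSize
  rr <- as.integer(refLocation[1]); rc <- as.integer(refLocation[2])
  if (rr < 1L || rc < 1L || rr > h - ps + 1L || rc > w - ps + 1L)
    stop("reference location out of bounds for this patch size")
  half <- (params@searchWindow - ps) %/% 2L
  r0 <- max(1L, rr - half); r1 <- min(h - ps + 1L, rr + half)
  c0 <- max(1L, rc - half); c1 <- min(w - ps + 1L, rc + half)
  candRow <- rep(r0:r1, times = c1 - c0 + 1L)
  candCol <- rep(c0:c1, each = r1 - r0 + 1L)
  lin <- candRow + (candCol - 1L) * h
  offs <- patchOffsets(ps, h)
  P <- matrix(px[outer(offs, lin, "+")], length(offs))
  refIdx <- which(candRow == rr & candCol == rc)
  d <- colSums((P - P[, refIdx])^2)
  notRef <- seq_along(d) != refIdx
  ord <- order(d, notRef, candRow,
               candCol)[seq_len(min(params@groupSize, length(d)))]
  new("PatchGroup",
      groupMatrix = P[, ord, drop = FALSE],
      locations = cbind(row = candRow[ord], col = candCol[ord]),
      referenceIndex = which(ord == refIdx),
      patchSize = ps)
}

#' Estimate clean singular values under additive Gaussian noise
#'
#' Each singular value of the noisy group matrix is deflated by the expected
#' noise energy p * sigma^2 and clamped at zero.  By default the square root
#' is applied after the clamp so the estimate has the units of a singular
#' value; \code{sqrtCorrection = FALSE} gives the un-rooted variant.
#'
#' @param singularValues non-increasing singular values of the noisy group.
#' @param groupSize number of patches p in the group.
#' @param sigma noise standard deviation (>= 0).
#' @param sqrtCorrection apply sqrt after the clamp (default TRUE).
#' @return Non-increasing, non-negative clean singular value estimates.
#' @examples
#' estimateCleanSingularValues(c(10, 3, 1), groupSize = 4, sigma = 1)
#' @export
estimateCleanSingularValues <- function(singularValues, groupSize, sigma,
                                        sqrtCorrection = TRUE) {
  if (sigma < 0) stop("sigma must be >= 0")
  est <- pmax(singularValues^2 - groupSize * sigma^2, 0)
  if (sqrtCorrection) est <- sqrt(est)
  est
}

#' Singular value weights for weighted nuclear norm shrinkage
#'
#' \code{w_t = s * sqrt(p) * sigma^2 / (cleanSV_t + gamma)}: small (noise
#' dominated) singular values receive large weights and are suppressed, large
#' (structure carrying) ones are barely touched.  The \code{sigma^2} factor
#' scales the shrinkage with the working noise level, which is what lets the
#' outer iterations of \code{\link{wnnmDenoise}} converge; with
#' \code{sigma = 1} the rule reduces to the noise-free form
#' \code{s * sqrt(p) / (cleanSV_t + gamma)}.
#'
#' @param cleanSingularValues non-negative estimates, non-increasing.
#' @param groupSize p, the number of patches in the group.
#' @param s positive scale constant.
#' @param gamma positive stabiliser (guards the division).
#' @param sigma working noise standard deviation (default 1: no scaling).
#' @return Non-negative weights, non-decreasing wherever the input decreases.
#' @examples
#' wnnmWeights(c(4, 1, 0), groupSize = 4, s = 1, gamma = 1)
#' @export
wnnmWeights <- function(cleanSingularValues, groupSize, s = 2 * sqrt(2),
                        gamma = 1e-6, sigma = 1) {
  if (gamma <= 0) stop("gamma must be > 0: it guards the denominator")
  if (s <= 0) stop("s must be > 0")
  s * sqrt(groupSize) * sigma^2 / (cleanSingularValues + gamma)
}

#' Weighted singular value thresholding
#'
#' The proximal operator of the weighted nuclear norm for non-decreasing
#' weights: decompose \code{N = U D V'} and shrink each diagonal entry to
#' \code{max(D_tt - w_t, 0)}.  The non-decreasing weight order (heavier
#' shrinkage for smaller singular values) is what makes this closed form the
#' exact minimiser; violating it is an error.
#'
#' @param mat numeric matrix to denoise.
#' @param weights non-negative weights, one per singular value,
#'   non-decreasing.
#' @return Matrix of the same size with shrunken singular values.
#' @examples
#' m <- diag(c(5, 2, 1))
#' round(weightedSVT(m, c(0.5, 0.5, 2)), 6)
#' @export
weightedSVT <- function(mat, weights) {
  k <- min(dim(mat))
  weights <- rep_len(weights, k)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diff(weights) < -1e-9))
    stop("weights must be non-decreasing for the closed-form solution")
  sv <- svd(mat)
  shrunk <- pmax(sv$d - weights, 0)
  keep <- shrunk > 0
  if (!any(keep)) return(matrix(0, nrow(mat), ncol(mat)))
  sv$u[, keep, drop = FALSE] %*%
    (shrunk[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Denoise one patch group
#'
#' Composes \code{\link{estimateCleanSingularValues}},
#' \code{\link{wnnmWeights}} and \code{\link{weightedSVT}} on the group
#' matrix; locations and reference index are preserved.
#'
#' @param group a \linkS4class{PatchGroup}.
#' @param sigma working noise standard deviation.
#' @param params a \linkS4class{WNNMParams}.
#' @return A denoised \linkS4class{PatchGroup}.
#' @export
solveGroup <- function(group, sigma, params = WNNMParams()) {
  G <- group@groupMatrix
  ctr <- NULL
  if (params@centerPatches) {
    ctr <- rowMeans(G)
    G <- G - ctr
  }
  p <- ncol(G)
  sv <- svd(G, nu = 0, nv = 0)$d
  shat <- estimateCleanSingularValues(sv, p, sigma, params@sqrtCorrection)
  w <- wnnmWeights(shat, p, params@s, params@gamma, sigma)
  Gd <- weightedSVT(G, w)
  if (!is.null(ctr)) Gd <- Gd + ctr
  initialize(group, groupMatrix = Gd)
}

#' Aggregate denoised patch groups into an image
#'
#' Every patch estimate is written back at its location; overlapping
#' estimates are averaged.  With \code{rankWeights} each group's patches
#' enter the average with weight 1 / (1 + r), r the number of singular values
#' the group retained, so strongly compressible (flat) groups dominate where
#' they overlap richer ones; uniform weights are the classical choice.
#'
#' @param groups list of \linkS4class{PatchGroup}s (denoised).
#' @param dim integer (rows, cols) of the output image.
#' @param rankWeights optional numeric vector of per-group aggregation
#'   weights; NULL means uniform.
#' @return A \linkS4class{GrayImage}.  Uncovered pixels are an error.
#' @export
aggregatePatches <- function(groups, dim, rankWeights = NULL) {
  h <- dim[1]; w <- dim[2]
  num <- numeric(h * w)
  den <- numeric(h * w)
  if (is.null(rankWeights)) rankWeights <- rep(1, length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    offs <- patchOffsets(g@patchSize, h)
    lin <- g@locations[, 1] + (g@locations[, 2] - 1L) * h
    idx <- outer(offs, lin, "+")
    wg <- rankWeights[gi]
    sums <- rowsum(c(g@groupMatrix) * wg, c(idx))
    at <- as.integer(rownames(sums))
    num[at] <- num[at] + sums[, 1]
    cnts <- rowsum(rep(wg, length(idx)), c(idx))
    den[at] <- den[at] + cnts[, 1]
  }
  if (any(den == 0))
    stop("aggregation left uncovered pixels; reference grid must cover ",
         "the whole image")
  GrayImage(matrix(num / den, h, w))
}

# One full extract -> match -> shrink -> aggregate sweep.  Identical in
# exact arithmetic to composing the exported operations, but the group SVD
# is taken through the symmetric eigendecomposition of G G' (d x d with
# d = patchSize^2 <= groupSize) and the denoised group is reconstructed from
# the retained left singular vectors only, which is considerably faster.
wnnmPass <- function(px, sigma, params) {
  h <- nrow(px); w <- ncol(px)
  ps <- params@patchSize
  offs <- patchOffsets(ps, h)
  grid <- referencePatchGrid(c(h, w), ps, params@step)
  half <- (params@searchWindow - ps) %/% 2L
  lastR <- h - ps + 1L; lastC <- w - ps + 1L
  num <- numeric(h * w); den <- numeric(h * w)
  sig2 <- sigma^2
  for (i in seq_len(nrow(grid))) {
    rr <- grid[i, 1]; rc <- grid[i, 2]
    r0 <- max(1L, rr - half); r1 <- min(lastR, rr + half)
    c0 <- max(1L, rc - half); c1 <- min(lastC, rc + half)
    candRow <- rep(r0:r1, times = c1 - c0 + 1L)
    candCol <- rep(c0:c1, each = r1 - r0 + 1L)
    lin <- candRow + (candCol - 1L) * h
    P <- matrix(px[outer(offs, lin, "+")], length(offs))
    refIdx <- which(candRow == rr & candCol == rc)
    d <- colSums((P - P[, refIdx])^2)
    notRef <- seq_along(d) != refIdx
    ord <- order(d, notRef, candRow, candCol)[
      seq_len(min(params@groupSize, length(d)))]
    G <- P[, ord, drop = FALSE]
    ctr <- NULL
    if (params@centerPatches) { ctr <- rowMeans(G); G <- G - ctr }
    p <- ncol(G)
    ev <- eigen(tcrossprod(G), symmetric = TRUE)
    sv <- sqrt(pmax(ev$values, 0))
    shat <- estimateCleanSingularValues(sv, p, sigma, params@sqrtCorrection)
    wts <- wnnmWeights(shat, p, params@s, params@gamma, sigma)
    shrunk <- pmax(sv - wts, 0)
    keep <- which(shrunk > 0)
    if (length(keep)) {
      Uk <- ev$vectors[, keep, drop = FALSE]
      Gd <- Uk %*% ((shrunk[keep] / sv[keep]) * (crossprod(Uk, G)))
    } else {
      Gd <- matrix(0, nrow(G), ncol(G))
    }
    if (!is.null(ctr)) Gd <- Gd + ctr
    wg <- 1 / (1 + length(keep))
    idx <- outer(offs, lin[ord], "+")
    sums <- rowsum(c(Gd) * wg, c(idx))
    at <- as.integer(rownames(sums))
    num[at] <- num[at] + sums[, 1]
    cnts <- rowsum(rep(wg, length(idx)), c(idx))
    den[at] <- den[at] + cnts[, 1]
  }
  matrix(num / den, h, w)
}

#' WNNM image denoising
#'
#' Iteratively regularised weighted nuclear norm minimisation.  Each round
#' forms the working image \code{n_k = m_{k-1} + delta * (n - m_{k-1})}
#' (with \code{m_0 = n}, the noisy input), re-estimates the residual noise
#' level as \code{noiseFactor * sqrt(max(sigma^2 - mean((n - n_k)^2), 0))},
#' then runs a full block-matching / weighted singular value shrinkage /
#' aggregation sweep.  Fully deterministic for fixed inputs.
#'
#' @param image noisy \linkS4class{GrayImage} or numeric matrix.
#' @param sigma noise standard deviation on the intensity scale of
#'   \code{image} (for normalised images, the sigma fraction itself).
#' @param params a \linkS4class{WNNMParams}.
#' @return The denoised \linkS4class{GrayImage}.
#' @examples
#' clean <- generatePhantom(48, 48)
#' noisy <- addGaussianNoise(clean, 0.25, seed = 7)
#' par <- WNNMParams(patchSize = 5, groupSize = 40, searchWindow = 20,
#'                   iters = 2)
#' den <- wnnmDenoise(noisy, 0.25, par)
#' mean((pixels(den) - pixels(clean))^2) < mean((pixels(noisy) - pixels(clean))^2)
#' @export
wnnmDenoise <- function(image, sigma, params = WNNMParams()) {
  if (sigma < 0) stop("sigma must be >= 0")
  noisy <- asPixels(image)
  if (nrow(noisy) < 8L || ncol(noisy) < 8L)
    stop("image must be at least 8 x 8")
  m <- noisy
  for (k in seq_len(params@iters)) {
    nk <- m + params@delta * (noisy - m)
    sigK <- params@noiseFactor *
      sqrt(max(sigma^2 - mean((noisy - nk)^2), 0))
    m <- wnnmPass(nk, sigK, params)
  }
  GrayImage(m)
}
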