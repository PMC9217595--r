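test_that("reference grid tiles exactly and clamps to the border", {
  expect_equal(referencePatchGrid(c(8, 8), 4, 4),
               cbind(row = c(1L, 5L, 1L, 5L), col = c(1L, 1L, 5L, 5L)))
  g <- referencePatchGrid(c(10, 10), 4, 4)
  expect_true(any(g[, 1] == 7 & g[, 2] == 7))   # clamped last index
  expect_true(all(g[, 1] <= 7 & g[, 2] <= 7))
  expect_equal(referencePatchGrid(c(6, 6), 6, 3), cbind(row = 1L, col = 1L))
  expect_error(referencePatchGrid(c(4, 4), 6, 2), "smaller")
})

test_that("block matching equals the exhaustive nearest-p oracle", {
  set.seed(77)
  px <- matrix(runif(32 * 32), 32, 32)
  params <- WNNMParams(patchSize = 4, groupSize = 12, searchWindow = 16)
  for (ref in list(c(5L, 5L), c(1L, 1L), c(29L, 20L))) {
    got <- blockMatch(px, ref, params)
    want <- bruteForceBlockMatch(px, ref, 4, 16, 12)
    expect_equal(unname(patchLocations(got)), unname(want))
    # reference member and distance ordering
    ri <- referenceIndex(got)
    expect_equal(unname(patchLocations(got)[ri, ]), as.integer(ref))
    ds <- colSums((groupMatrix(got) - groupMatrix(got)[, ri])^2)
    expect_true(all(diff(ds) >= -1e-12))
  }
})

test_that("block matching on a tiled image finds exact duplicates", {
  tile <- matrix(runif(16), 4, 4)
  px <- tile[rep(1:4, 4), rep(1:4, 4)]  # 16x16 of identical 4x4 patches
  params <- WNNMParams(patchSize = 4, groupSize = 6, searchWindow = 12)
  g <- blockMatch(px, c(5L, 5L), params)
  ds <- colSums((groupMatrix(g) - groupMatrix(g)[, referenceIndex(g)])^2)
  expect_equal(ncol(groupMatrix(g)), 6)
  expect_equal(sum(ds), 0)
})

test_that("clean singular value estimation applies the clamp and sqrt", {
  sv <- c(10, 4, 2)
  expect_equal(estimateCleanSingularValues(sv, 4, 0), sv)
  # below the noise floor: clamped to zero
  expect_equal(estimateCleanSingularValues(2, 4, 1.5), 0)
  # literal (un-rooted) variant
  expect_equal(estimateCleanSingularValues(4, 4, 1, sqrtCorrection = FALSE),
               12)
  expect_equal(estimateCleanSingularValues(4, 4, 1), sqrt(12))
  expect_error(estimateCleanSingularValues(sv, 4, -1), ">= 0")
})

test_that("rank-1 groups recover their leading singular value in the mean", {
  patch <- runif(16)  # fixed direction; draws vary the noise only
  p <- 12; sigma <- 0.1
  trueSV <- sqrt(sum(patch^2) * p)
  set.seed(101)
  est <- replicate(200, {
    G <- matrix(patch, 16, p) + matrix(rnorm(16 * p, 0, sigma), 16, p)
    estimateCleanSingularValues(svd(G, nu = 0, nv = 0)$d[1], p, sigma)
  })
  expect_lt(abs(mean(est) - trueSV) / trueSV, 0.05)
})

test_that("weights are maximal at zero estimate and anti-monotone", {
  expect_equal(wnnmWeights(0, 4, s = 1, gamma = 0.5), 1 * 2 / 0.5)
  expect_equal(wnnmWeights(1, 4, s = 1, gamma = 1), 1)  # s sqrt(p)/(1+1)
  sv <- sort(runif(10, 0, 5), decreasing = TRUE)
  w <- wnnmWeights(sv, 20)
  expect_true(all(diff(w) >= 0))
  # sigma^2 scaling: quadruples the weight at double the noise
  expect_equal(wnnmWeights(1, 4, s = 1, gamma = 1, sigma = 2),
               4 * wnnmWeights(1, 4, s = 1, gamma = 1, sigma = 1))
  expect_error(wnnmWeights(1, 4, gamma = 0), "gamma")
})

test_that("weighted SVT matches the per-singular-value grid oracle", {
  set.seed(300)
  for (n in c(3L, 5L)) {
    for (rep in 1:8) {
      mat <- matrix(rnorm(n * n), n, n)
      w <- sort(runif(n, 0, 2))
      got <- weightedSVT(mat, w)
      want <- gridSVTOracle(mat, w)
      expect_lt(max(abs(got - want)), 1e-6)
      # shrinkage invariant: output singular values never exceed input's
      expect_true(all(svd(got)$d <= svd(mat)$d + 1e-12))
    }
  }
})

test_that("weighted SVT honours its limit cases and weight-order contract", {
  m <- matrix(rnorm(12), 3, 4)
  expect_lt(max(abs(weightedSVT(m, c(0, 0, 0)) - m)), 1e-12)
  big <- svd(m)$d[1] + 1
  expect_equal(weightedSVT(m, rep(big, 3)), matrix(0, 3, 4))
  expect_error(weightedSVT(m, c(2, 1, 3)), "non-decreasing")
})

test_that("solveGroup denoises a rank-1 group and passes degenerate input", {
  params <- WNNMParams(patchSize = 4, groupSize = 10)
  patch <- runif(16, 0.3, 0.7)
  set.seed(11)
  G <- matrix(patch, 16, 10) + matrix(rnorm(160, 0, 0.1), 16, 10)
  grp <- new("PatchGroup", groupMatrix = G,
             locations = cbind(rep(1:5, 2), rep(1:2, each = 5)),
             referenceIndex = 1L, patchSize = 4L)
  out <- solveGroup(grp, 0.1, params)
  spreadIn <- mean(apply(G, 1, sd))
  spreadOut <- mean(apply(groupMatrix(out), 1, sd))
  expect_lt(spreadOut, spreadIn)  # columns pulled together
  expect_equal(patchLocations(out), patchLocations(grp))

  zero <- initialize(grp, groupMatrix = matrix(0, 16, 10))
  expect_equal(groupMatrix(solveGroup(zero, 0.2, params)),
               matrix(0, 16, 10))

  # sigma = 0 with a huge gamma: weights vanish, group passes through
  loose <- WNNMParams(patchSize = 4, groupSize = 10, gamma = 1e9)
  expect_lt(max(abs(groupMatrix(solveGroup(grp, 0, loose)) - G)), 1e-6)
})

test_that("aggregation averages overlaps and demands full coverage", {
  # single full-image patch: returned verbatim
  px <- matrix(runif(16), 4, 4)
  g <- new("PatchGroup", groupMatrix = matrix(px, 16, 1),
           locations = cbind(1L, 1L), referenceIndex = 1L, patchSize = 4L)
  expect_equal(pixels(aggregatePatches(list(g), c(4, 4))), px)

  # two overlapping constant patches differing by c: overlap at the mean
  g2 <- new("PatchGroup",
            groupMatrix = cbind(rep(0.2, 4), rep(0.6, 4)),
            locations = cbind(c(1L, 1L), c(1L, 2L)),
            referenceIndex = 1L, patchSize = 2L)
  out <- pixels(aggregatePatches(list(g2), c(2, 3)))
  expect_equal(out[, 2], c(0.4, 0.4))
  expect_equal(out[, 1], c(0.2, 0.2))
  expect_equal(out[, 3], c(0.6, 0.6))

  expect_error(aggregatePatches(list(g2), c(2, 4)), "uncovered")
})

test_that("one denoising sweep equals the composition of exported ops", {
  set.seed(55)
  clean <- smallPhantom(24)
  noisy <- pixels(addGaussianNoise(clean, 0.2, seed = 3))
  params <- WNNMParams(patchSize = 4, groupSize = 20, searchWindow = 12,
                       step = 3, iters = 1L, delta = 0, noiseFactor = 1)
  # composed route: exported operations, rank-based aggregation weights
  grid <- referencePatchGrid(dim(noisy), 4, 3)
  groups <- list(); ranks <- numeric(0)
  for (i in seq_len(nrow(grid))) {
    grp <- blockMatch(noisy, grid[i, ], params)
    den <- solveGroup(grp, 0.2, params)
    groups[[i]] <- den
    ranks[i] <- sum(svd(groupMatrix(den), nu = 0, nv = 0)$d > 1e-10)
  }
  composed <- aggregatePatches(groups, dim(noisy),
                               rankWeights = 1 / (1 + ranks))
  direct <- wnnmDenoise(noisy, 0.2, params)
  expect_lt(max(abs(pixels(composed) - pixels(direct))), 1e-8)
})

test_that("denoising limits: constant images and zero noise", {
  const <- GrayImage(matrix(0.4, 16, 16))
  params <- WNNMParams(patchSize = 4, groupSize = 12, searchWindow = 12,
                       iters = 1L)
  out <- wnnmDenoise(const, 0, params)
  expect_lt(max(abs(pixels(out) - 0.4)), 1e-10)

  clean <- smallPhantom(24, smoothSigma = 1)
  out2 <- wnnmDenoise(clean, 0, params)
  expect_lt(mean(abs(pixels(out2) - pixels(clean))), 0.01)
})

test_that("denoising is deterministic and improves a noisy phantom", {
  clean <- smallPhantom(32, smoothSigma = 1)
  noisy <- addGaussianNoise(clean, 0.25, seed = 8)
  params <- WNNMParams(patchSize = 5, groupSize = 40, searchWindow = 20,
                       step = 3, iters = 4L)
  a <- wnnmDenoise(noisy, 0.25, params)
  b <- wnnmDenoise(noisy, 0.25, params)
  expect_identical(pixels(a), pixels(b))
  expect_gt(imagePSNR(pixels(clean), pixels(a)),
            imagePSNR(pixels(clean), pixels(noisy)) + 3)
})
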