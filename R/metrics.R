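checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions")
}

#' Mean squared error between two images
#'
#' @param a,b images of identical size (GrayImage or matrix).
#' @return Mean of squared per-pixel differences.
#' @examples
#' imageMSE(matrix(0, 2, 2), matrix(0.1, 2, 2))
#' @export
imageMSE <- function(a, b) {
  a <- asPixels(a); b <- asPixels(b)
  checkSameShape(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(maxValue^2 / MSE)} in decibels; identical images give
#' \code{Inf}.
#'
#' @param a,b images of identical size.
#' @param maxValue dynamic range constant (1 for normalised images).
#' @return PSNR in dB.
#' @examples
#' imagePSNR(matrix(0, 2, 2), matrix(0.1, 2, 2))  # 20 dB
#' @export
imagePSNR <- function(a, b, maxValue = 1) {
  if (maxValue <= 0) stop("maxValue must be > 0")
  m <- imageMSE(a, b)
  if (m == 0) return(Inf)
  10 * log10(maxValue^2 / m)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sd 1.5) and the standard
#' stabilisers \code{C1 = (K1 * maxValue)^2}, \code{C2 = (K2 * maxValue)^2}.
#' Local statistics are computed only where the window lies fully inside the
#' image, so no boundary extrapolation enters the score.
#'
#' @param a,b images of identical size, at least the window size.
#' @param maxValue dynamic range constant.
#' @param windowSize odd window side length (default 11).
#' @param windowSigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 stabiliser fractions (defaults 0.01 and 0.03).
#' @return Mean SSIM in [-1, 1].
#' @examples
#' img <- generatePhantom(32, 32)
#' imageSSIM(img, img)  # exactly 1
#' @export
imageSSIM <- function(a, b, maxValue = 1, windowSize = 11L,
                      windowSigma = 1.5, K1 = 0.01, K2 = 0.03) {
  a <- asPixels(a); b <- asPixels(b)
  checkSameShape(a, b)
  if (windowSize %% 2L != 1L) stop("windowSize must be odd")
  if (nrow(a) < windowSize || ncol(a) < windowSize)
    stop("images smaller than the SSIM window")
  r <- (windowSize - 1L) %/% 2L
  k <- stats::dnorm(seq(-r, r), sd = windowSigma)
  k <- k / sum(k)
  W <- outer(k, k)
  convValid <- function(x) {
    h <- nrow(x); w <- ncol(x)
    out <- matrix(0, h - windowSize + 1L, w - windowSize + 1L)
    for (i in seq_len(windowSize))
      for (j in seq_len(windowSize))
        out <- out + W[i, j] *
          x[i:(h - windowSize + i), j:(w - windowSize + j)]
    out
  }
  C1 <- (K1 * maxValue)^2
  C2 <- (K2 * maxValue)^2
  muA <- convValid(a); muB <- convValid(b)
  varA <- convValid(a^2) - muA^2
  varB <- convValid(b^2) - muB^2
  covAB <- convValid(a * b) - muA * muB
  ssimMap <- ((2 * muA * muB + C1) * (2 * covAB + C2)) /
    ((muA^2 + muB^2 + C1) * (varA + varB + C2))
  mean(ssimMap)
}

#' Full quality report for a reference / test image pair
#'
#' @param ref clean reference image.
#' @param test image under evaluation.
#' @param maxValue dynamic range constant shared by PSNR and SSIM.
#' @return A \linkS4class{MetricReport}.
#' @examples
#' clean <- generatePhantom(32, 32)
#' noisy <- addGaussianNoise(clean, 0.1, seed = 2)
#' imageMetrics(clean, noisy)
#' @export
imageMetrics <- function(ref, test, maxValue = 1) {
  m <- imageMSE(ref, test)
  new("MetricReport",
      psnr = if (m == 0) Inf else 10 * log10(maxValue^2 / m),
      ssim = imageSSIM(ref, test, maxValue = maxValue),
      mse = m,
      maxValue = maxValue)
}
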