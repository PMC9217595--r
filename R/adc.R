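#' Mono-exponential DWI signal decay
#'
#' \code{S(b) = S0 * exp(-b * adc)} evaluated element-wise; the forward model
#' behind every ADC computation in this package.
#'
#' @param s0 signal at b = 0 (scalar, vector or matrix).
#' @param b diffusion weighting in s/mm^2.
#' @param adc apparent diffusion coefficient in mm^2/s.
#' @return Signal with the shape of \code{s0}.
#' @examples
#' dwiSignal(1000, 800, 1e-3)
#' @export
dwiSignal <- function(s0, b, adc) s0 * exp(-b * adc)

#' ADC map from a single b value
#'
#' Per-pixel \code{ADC = ln(S(0) / S(b)) / b} under the mono-exponential
#' model.  Pixels where either signal is non-positive are masked out rather
#' than producing infinities.
#'
#' @param stack a \linkS4class{DWIStack}.
#' @param b a nonzero b value present in the stack.
#' @return An \linkS4class{ADCMap}.
#' @examples
#' s0 <- matrix(1000, 4, 4)
#' st <- DWIStack(list(s0, dwiSignal(s0, 800, 1e-3)), c(0, 800))
#' adcValues(computeADC(st, 800))[1, 1]
#' @export
computeADC <- function(stack, b) {
  i <- match(b, stack@bValues)
  if (is.na(i)) stop("b value ", b, " not present in stack")
  if (b == 0) stop("ADC needs a nonzero b value")
  d <- dim(stack@signals)
  s0 <- matrix(stack@signals[, , 1], d[1], d[2])
  sb <- matrix(stack@signals[, , i], d[1], d[2])
  mask <- s0 > 0 & sb > 0
  vals <- matrix(NA_real_, nrow(s0), ncol(s0))
  vals[mask] <- log(s0[mask] / sb[mask]) / b
  new("ADCMap", values = vals, mask = mask, bUsed = as.character(b))
}

#' ADC map by least-squares over all b values
#'
#' Per-pixel ordinary least squares slope of \code{-log(S)} against b, using
#' every acquisition in the stack (including b = 0).  Pixels with any
#' non-positive signal are masked out.
#'
#' @param stack a \linkS4class{DWIStack} with at least two b values.
#' @return An \linkS4class{ADCMap} with \code{bUsed = "fit"}.
#' @examples
#' s0 <- matrix(1000, 4, 4)
#' st <- DWIStack(list(s0, dwiSignal(s0, 600, 1e-3), dwiSignal(s0, 1000, 1e-3)),
#'                c(0, 600, 1000))
#' adcValues(fitADCMultiB(st))[1, 1]
#' @export
fitADCMultiB <- function(stack) {
  b <- stack@bValues
  if (length(unique(b)) < 2L) stop("need at least two distinct b values")
  d <- dim(stack@signals)
  S <- matrix(stack@signals, d[1] * d[2], d[3])
  mask <- rowSums(S <= 0) == 0
  vals <- rep(NA_real_, nrow(S))
  if (any(mask)) {
    y <- -log(S[mask, , drop = FALSE])
    bc <- b - mean(b)
    # slope of y on b, closed form, vectorised across pixels
    vals[mask] <- (y %*% bc) / sum(bc^2)
  }
  new("ADCMap", values = matrix(vals, d[1], d[2]),
      mask = matrix(mask, d[1], d[2]), bUsed = "fit")
}

#' Simulate a two-class chemotherapy-response cohort
#'
#' Each case carries a small lesion of \code{lesionPixels} pixels with a
#' case-level true ADC drawn from its class Gaussian (responders vs
#' non-responders).  Signals follow the mono-exponential decay from a common
#' \code{s0}, perturbed by additive Gaussian noise whose standard deviation
#' is \code{noiseFractions[b] * s0}, so acquisition quality can differ by b.
#' Per-case scores are the mean lesion ADC recomputed from the noisy signals
#' at each nonzero b and from the multi-b least squares fit.
#'
#' @param nResponder,nNonresponder class sizes (>= 1).
#' @param adcMeans named numeric: class mean ADC (mm^2/s) for
#'   \code{responder} and \code{nonresponder}.  Responders sit higher:
#'   effective chemotherapy raises lesion ADC as cellularity drops.
#' @param adcSd between-case standard deviation of true ADC (> 0).
#' @param bValues acquisition b values, starting at 0.
#' @param noiseFractions per-b signal noise as a fraction of \code{s0}; one
#'   value per b.  Effective per-acquisition SNR reflects averaging and
#'   parallel-imaging choices as well as diffusion weighting, so it need
#'   not fall monotonically with b; the defaults emulate a protocol whose
#'   b = 800 acquisition is the best conditioned while SNR collapses at
#'   b = 1000.
#' @param lesionPixels pixels per lesion (averaging support of the score).
#' @param s0 baseline signal amplitude.
#' @param seed integer RNG seed (NULL: current stream).
#' @return A data.frame with one row per case: \code{case},
#'   \code{responder} (logical), \code{adcTrue}, one \code{adc_<b>} score
#'   column per nonzero b and \code{adc_fit} for the least-squares score.
#' @examples
#' coh <- simulateResponseCohort(10, 10, seed = 1)
#' head(coh)
#' @export
simulateResponseCohort <- function(nResponder = 59L, nNonresponder = 59L,
                                   adcMeans = c(responder = 1.2e-3,
                                                nonresponder = 1.0e-3),
                                   adcSd = 1e-4,
                                   bValues = c(0, 600, 800, 1000),
                                   noiseFractions = c(0.01, 0.15, 0.03, 0.25),
                                   lesionPixels = 25L,
                                   s0 = 1000,
                                   seed = NULL) {
  if (nResponder < 1L || nNonresponder < 1L) stop("class sizes must be >= 1")
  if (adcSd <= 0 || any(adcMeans <= 0))
    stop("ADC distribution parameters must be positive")
  if (length(noiseFractions) != length(bValues))
    stop("need one noise fraction per b value")
  if (bValues[1] != 0) stop("bValues must start at 0")
  n <- nResponder + nNonresponder
  responder <- rep(c(TRUE, FALSE), c(nResponder, nNonresponder))
  withSeed(seed, {
    adcTrue <- stats::rnorm(n,
      ifelse(responder, adcMeans[["responder"]], adcMeans[["nonresponder"]]),
      adcSd)
    nb <- length(bValues)
    scores <- matrix(NA_real_, n, nb)  # per-b ADC estimates (col 1 unused)
    fitScores <- numeric(n)
    for (i in seq_len(n)) {
      Sclean <- outer(rep(1, lesionPixels), bValues,
                      function(one, b) dwiSignal(s0, b, adcTrue[i]))
      noise <- matrix(stats::rnorm(lesionPixels * nb), lesionPixels, nb) *
        rep(noiseFractions * s0, each = lesionPixels)
      S <- Sclean + noise
      stack <- DWIStack(array(S, dim = c(lesionPixels, 1L, nb)), bValues)
      for (j in seq_along(bValues)[-1]) {
        m <- computeADC(stack, bValues[j])
        scores[i, j] <- mean(adcValues(m)[validMask(m)])
      }
      fit <- fitADCMultiB(stack)
      fitScores[i] <- mean(adcValues(fit)[validMask(fit)])
    }
    out <- data.frame(case = seq_len(n), responder = responder,
                      adcTrue = adcTrue)
    for (j in seq_along(bValues)[-1])
      out[[paste0("adc_", bValues[j])]] <- scores[, j]
    out$adc_fit <- fitScores
    out
  })
}
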