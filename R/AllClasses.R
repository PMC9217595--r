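#' @import methods
NULL

#' GrayImage: a 2D grayscale intensity field
#'
#' Thin S4 wrapper around a numeric matrix holding image intensities on a
#' nominal [0, 1] scale.  Noisy images may exceed the nominal range: noise
#' addition never clips, because clipping would distort the Gaussian noise
#' model every denoiser here assumes.
#'
#' @slot .Data numeric matrix of pixel intensities (rows = image rows).
#' @export
setClass("GrayImage", contains = "matrix")

setValidity("GrayImage", function(object) {
  if (!is.numeric(object@.Data)) return("pixels must be numeric")
  if (length(dim(object@.Data)) != 2L) return("pixels must be a 2D matrix")
  if (anyNA(object@.Data)) return("pixels must not contain NA")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities.
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(0.5, 16, 16))
#' dim(img)
#' @export
GrayImage <- function(pixels) {
  new("GrayImage", as.matrix(pixels))
}

#' @describeIn GrayImage-class extract the pixel matrix.
#' @param x a GrayImage.
#' @export
pixels <- function(x) {
  if (is(x, "GrayImage")) x@.Data else as.matrix(x)
}

setMethod("show", "GrayImage", function(object) {
  px <- object@.Data
  cat(sprintf("GrayImage %d x %d, range [%.4g, %.4g], mean %.4g\n",
              nrow(px), ncol(px), min(px), max(px), mean(px)))
})

#' WNNMParams: operating parameters of the WNNM denoiser
#'
#' @slot patchSize side length (pixels) of the square patches.
#' @slot groupSize number p of similar patches stacked per group (clipped to
#'   the candidates actually available in the search window).
#' @slot searchWindow side length (pixels) of the block-matching search
#'   neighbourhood centred on the reference patch.
#' @slot step stride between reference patches; the last row/column of the
#'   reference grid is clamped to the image border so coverage is complete.
#' @slot s positive scale constant of the singular-value weight rule.
#' @slot gamma positive stabiliser keeping the weight denominator away from 0.
#' @slot iters number K of outer iterative-regularisation rounds.
#' @slot delta relaxation factor in [0, 1) feeding residual noise back into
#'   the working image between rounds.
#' @slot noiseFactor scale in (0, 1] applied to the per-round re-estimated
#'   noise level (the raw estimate overstates the residual noise at the
#'   fixed point of the outer loop; see the methods vignette).
#' @slot sqrtCorrection apply the square root after the variance-subtraction
#'   clamp when estimating clean singular values (dimensionally consistent
#'   form); FALSE reproduces the un-rooted literal rule.
#' @slot centerPatches subtract each group's column mean before the SVD
#'   (off by default; the grouping model carries no centring term).
#' @export
setClass("WNNMParams",
  representation(patchSize = "integer", groupSize = "integer",
                 searchWindow = "integer", step = "integer",
                 s = "numeric", gamma = "numeric",
                 iters = "integer", delta = "numeric",
                 noiseFactor = "numeric",
                 sqrtCorrection = "logical", centerPatches = "logical"))

setValidity("WNNMParams", function(object) {
  if (object@patchSize < 2L) return("patchSize must be >= 2")
  if (object@groupSize < 1L) return("groupSize must be >= 1")
  if (object@searchWindow < object@patchSize)
    return("searchWindow must be >= patchSize")
  if (object@step < 1L) return("step must be >= 1")
  if (object@s <= 0) return("s must be > 0")
  if (object@gamma <= 0) return("gamma must be > 0 (division guard)")
  if (object@iters < 1L) return("iters must be >= 1")
  if (object@delta < 0 || object@delta >= 1) return("delta must be in [0, 1)")
  if (object@noiseFactor <= 0 || object@noiseFactor > 1)
    return("noiseFactor must be in (0, 1]")
  TRUE
})

#' Construct WNNM parameters
#'
#' Defaults are the package's operating point for heavy noise (sigma at 25
#' to 50 percent of the dynamic range): 9x9 patches, groups of 140, a 40 px
#' search window, stride 4, weight scale 2*sqrt(2), 14 outer rounds with
#' relaxation 0.1.  The methods vignette discusses how this point was chosen.
#'
#' @param patchSize,groupSize,searchWindow,step,s,gamma,iters,delta,noiseFactor,sqrtCorrection,centerPatches
#'   see the corresponding slots of \linkS4class{WNNMParams}.
#' @return A validated \linkS4class{WNNMParams} object.
#' @examples
#' WNNMParams(patchSize = 6, groupSize = 60, iters = 1)
#' @export
WNNMParams <- function(patchSize = 9L, groupSize = 140L, searchWindow = 40L,
                       step = 4L, s = 2 * sqrt(2), gamma = 1e-6,
                       iters = 14L, delta = 0.1, noiseFactor = 0.7,
                       sqrtCorrection = TRUE, centerPatches = FALSE) {
  new("WNNMParams",
      patchSize = as.integer(patchSize), groupSize = as.integer(groupSize),
      searchWindow = as.integer(searchWindow), step = as.integer(step),
      s = s, gamma = gamma, iters = as.integer(iters), delta = delta,
      noiseFactor = noiseFactor,
      sqrtCorrection = isTRUE(sqrtCorrection),
      centerPatches = isTRUE(centerPatches))
}

setMethod("show", "WNNMParams", function(object) {
  cat(sprintf(paste0(
    "WNNMParams: patch %d, group %d, window %d, step %d\n",
    "  s = %.4g, gamma = %.3g, iters = %d, delta = %.3g, noiseFactor = %.3g\n",
    "  sqrtCorrection = %s, centerPatches = %s\n"),
    object@patchSize, object@groupSize, object@searchWindow, object@step,
    object@s, object@gamma, object@iters, object@delta, object@noiseFactor,
    object@sqrtCorrection, object@centerPatches))
})

#' PatchGroup: a stack of vectorised similar patches
#'
#' Columns of \code{groupMatrix} are vectorised patches (column-major within
#' the patch), ordered by ascending squared distance to the reference patch
#' with ties broken by raster order of location.
#'
#' @slot groupMatrix d x p numeric matrix, d = patchSize^2.
#' @slot locations p x 2 integer matrix of 1-based top-left (row, col)
#'   patch coordinates, one row per column of \code{groupMatrix}.
#' @slot referenceIndex column index of the reference patch.
#' @slot patchSize patch side length.
#' @export
setClass("PatchGroup",
  representation(groupMatrix = "matrix", locations = "matrix",
                 referenceIndex = "integer", patchSize = "integer"))

setValidity("PatchGroup", function(object) {
  p <- ncol(object@groupMatrix)
  if (p < 1L) return("group must contain at least one patch")
  if (nrow(object@locations) != p)
    return("locations must have one row per patch")
  if (ncol(object@locations) != 2L) return("locations must be p x 2")
  if (object@referenceIndex < 1L || object@referenceIndex > p)
    return("referenceIndex out of range")
  if (nrow(object@groupMatrix) != object@patchSize^2)
    return("groupMatrix row count must equal patchSize^2")
  TRUE
})

#' @describeIn PatchGroup-class the d x p matrix of vectorised patches.
#' @param x a PatchGroup.
#' @export
groupMatrix <- function(x) x@groupMatrix

#' @describeIn PatchGroup-class the p x 2 matrix of patch top-left locations.
#' @export
patchLocations <- function(x) x@locations

#' @describeIn PatchGroup-class index of the reference patch column.
#' @export
referenceIndex <- function(x) x@referenceIndex

setMethod("show", "PatchGroup", function(object) {
  cat(sprintf("PatchGroup: %d patches of %dx%d (reference column %d)\n",
              ncol(object@groupMatrix), object@patchSize, object@patchSize,
              object@referenceIndex))
})

#' DWIStack: co-registered diffusion-weighted signal images
#'
#' @slot signals numeric 3D array (rows x cols x b) of signal intensities,
#'   one slice per b value, common arbitrary units.
#' @slot bValues strictly increasing diffusion weightings in s/mm^2; the
#'   first must be 0 (the reference acquisition).
#' @export
setClass("DWIStack",
  representation(signals = "array", bValues = "numeric"))

setValidity("DWIStack", function(object) {
  d <- dim(object@signals)
  if (length(d) != 3L) return("signals must be a 3D array")
  if (d[3] != length(object@bValues))
    return("third dimension must match the number of b values")
  if (length(object@bValues) < 2L) return("need at least two b values")
  if (object@bValues[1] != 0) return("first b value must be 0")
  if (any(diff(object@bValues) <= 0))
    return("b values must be strictly increasing")
  TRUE
})

#' Construct a DWIStack
#'
#' @param signals a 3D array, or a list of equally sized matrices (one per b).
#' @param bValues numeric vector of b values, starting at 0, increasing.
#' @return A \linkS4class{DWIStack}.
#' @examples
#' s0 <- matrix(1000, 8, 8)
#' DWIStack(list(s0, s0 * exp(-800 * 1e-3)), c(0, 800))
#' @export
DWIStack <- function(signals, bValues) {
  if (is.list(signals)) {
    dm <- dim(signals[[1]])
    signals <- array(unlist(signals, use.names = FALSE),
                     dim = c(dm, length(signals)))
  }
  new("DWIStack", signals = signals, bValues = as.numeric(bValues))
}

#' @describeIn DWIStack-class the vector of b values.
#' @param x a DWIStack.
#' @export
bValues <- function(x) x@bValues

#' @describeIn DWIStack-class the signal image at one b value.
#' @param b a b value present in the stack.
#' @export
signalAt <- function(x, b) {
  i <- match(b, x@bValues)
  if (is.na(i)) stop("b value ", b, " not present in stack")
  GrayImage(x@signals[, , i])
}

setMethod("show", "DWIStack", function(object) {
  cat(sprintf("DWIStack: %d x %d pixels, b = {%s} s/mm^2\n",
              dim(object@signals)[1], dim(object@signals)[2],
              paste(object@bValues, collapse = ", ")))
})

#' ADCMap: per-pixel apparent diffusion coefficient
#'
#' @slot values ADC in mm^2/s; NA outside the valid mask.
#' @slot mask logical matrix, TRUE where ADC could be computed.
#' @slot bUsed which b value (or "fit" for the multi-b least-squares slope)
#'   produced the map.
#' @export
setClass("ADCMap",
  representation(values = "matrix", mask = "matrix", bUsed = "character"))

setValidity("ADCMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must share dimensions")
  if (any(!is.finite(object@values[object@mask])))
    return("values must be finite on the valid mask")
  TRUE
})

#' @describeIn ADCMap-class the ADC value matrix (NA off-mask).
#' @param x an ADCMap.
#' @export
adcValues <- function(x) x@values

#' @describeIn ADCMap-class logical validity mask.
#' @export
validMask <- function(x) x@mask

setMethod("show", "ADCMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("ADCMap (%s): %d x %d, %d valid px, median %.3g mm^2/s\n",
              object@bUsed, nrow(object@values), ncol(object@values),
              sum(object@mask), stats::median(v)))
})

#' MetricReport: the PSNR / SSIM / MSE quality triad
#'
#' @slot psnr peak signal-to-noise ratio in dB (Inf for identical images).
#' @slot ssim mean local structural similarity in [-1, 1].
#' @slot mse mean squared error in squared intensity units.
#' @slot maxValue dynamic-range constant used by PSNR and SSIM.
#' @export
setClass("MetricReport",
  representation(psnr = "numeric", ssim = "numeric", mse = "numeric",
                 maxValue = "numeric"))

setValidity("MetricReport", function(object) {
  if (object@mse < 0) return("mse must be >= 0")
  if (object@ssim > 1 + 1e-12) return("ssim must be <= 1")
  if (object@mse > 0) {
    expected <- 10 * log10(object@maxValue^2 / object@mse)
    if (abs(expected - object@psnr) > 1e-9)
      return("psnr inconsistent with mse (10*log10(max^2/mse))")
  }
  TRUE
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: PSNR %.2f dB, SSIM %.4f, MSE %.3g (max %.3g)\n",
              object@psnr, object@ssim, object@mse, object@maxValue))
})

#' ROCResult: an empirical ROC curve with its summary
#'
#' Scores are oriented so that larger values indicate the positive class.
#'
#' @slot thresholds decreasing score cut-points (positive when score >= t).
#' @slot sensitivity,specificity per-threshold rates in [0, 1].
#' @slot auc trapezoidal area under the curve (midrank tie convention, so
#'   identical to the normalised Mann-Whitney U statistic).
#' @slot optimal named vector (threshold, sensitivity, specificity) at the
#'   maximum Youden index, ties resolved toward the lower threshold.
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric",
                 optimal = "numeric"))

setValidity("ROCResult", function(object) {
  n <- length(object@thresholds)
  if (length(object@sensitivity) != n || length(object@specificity) != n)
    return("sensitivity/specificity must align with thresholds")
  if (any(object@sensitivity < -1e-12 | object@sensitivity > 1 + 1e-12))
    return("sensitivity out of [0, 1]")
  if (any(object@specificity < -1e-12 | object@specificity > 1 + 1e-12))
    return("specificity out of [0, 1]")
  if (object@auc < 0 || object@auc > 1) return("auc out of [0, 1]")
  TRUE
})

#' @describeIn ROCResult-class the area under the curve.
#' @param x a ROCResult.
#' @export
rocAUC <- function(x) x@auc

#' @describeIn ROCResult-class the Youden-optimal operating point.
#' @export
rocOptimal <- function(x) x@optimal

#' @describeIn ROCResult-class the full curve as a data.frame.
#' @export
rocCurve <- function(x) {
  data.frame(threshold = x@thresholds, sensitivity = x@sensitivity,
             specificity = x@specificity)
}

setMethod("show", "ROCResult", function(object) {
  cat(sprintf(
    "ROCResult: AUC %.3f; optimal threshold %.4g (sens %.3f, spec %.3f)\n",
    object@auc, object@optimal[["threshold"]],
    object@optimal[["sensitivity"]], object@optimal[["specificity"]]))
})
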