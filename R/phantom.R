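#' Elliptical lesion descriptors for synthetic phantoms
#'
#' A blob is an ellipse given by its centre (row, col, in pixels), semi-axes
#' (pixels), rotation angle (radians) and fill intensity in [0, 1].
#'
#' @param centerRow,centerCol ellipse centre in pixel coordinates.
#' @param radiusRow,radiusCol semi-axis lengths in pixels.
#' @param angle rotation in radians.
#' @param intensity fill value in [0, 1].
#' @return A one-row data.frame; rbind several to describe a phantom.
#' @examples
#' rbind(phantomBlob(40, 40, 15, 10, 0.4, 0.8),
#'       phantomBlob(90, 70, 10, 18, -0.3, 0.6))
#' @export
phantomBlob <- function(centerRow, centerCol, radiusRow, radiusCol,
                        angle = 0, intensity = 0.8) {
  data.frame(centerRow = centerRow, centerCol = centerCol,
             radiusRow = radiusRow, radiusCol = radiusCol,
             angle = angle, intensity = intensity)
}

#' Default lesion layout for a phantom of the given size
#'
#' Three ellipses of intensity 0.5-0.9 scaled to the frame; the stand-in for
#' a single-slice DWI lesion pattern used throughout the package defaults.
#'
#' @param height,width frame size in pixels.
#' @return A blobs data.frame as accepted by \code{\link{generatePhantom}}.
#' @export
defaultBlobs <- function(height, width) {
  rbind(
    phantomBlob(0.35 * height, 0.30 * width, 0.18 * height, 0.12 * width,
                0.5, 0.8),
    phantomBlob(0.60 * height, 0.65 * width, 0.12 * height, 0.20 * width,
                -0.4, 0.6),
    phantomBlob(0.75 * height, 0.30 * width, 0.08 * height, 0.08 * width,
                0, 0.9))
}

randomBlobs <- function(height, width, n = 3L) {
  # caller provides a seeded RNG; keep every ellipse fully inside the frame
  blobs <- lapply(seq_len(n), function(i) {
    rr <- stats::runif(1, 0.06, 0.16) * height
    rc <- stats::runif(1, 0.06, 0.16) * width
    m <- max(rr, rc)
    phantomBlob(stats::runif(1, m + 1, height - m - 1),
                stats::runif(1, m + 1, width - m - 1),
                rr, rc, stats::runif(1, -pi / 2, pi / 2),
                stats::runif(1, 0.5, 0.9))
  })
  do.call(rbind, blobs)
}

#' Generate a piecewise-smooth anatomical phantom
#'
#' Constant background with elliptical lesion-like blobs, optionally softened
#' by a Gaussian blur.  Stands in for a single DWI slice so denoisers and
#' metrics can be exercised without patient data.
#'
#' @param height,width image size in pixels.
#' @param background background intensity in [0, 1].
#' @param blobs a data.frame of \code{\link{phantomBlob}} rows, or NULL to
#'   draw lesion geometry at random (requires \code{seed}).
#' @param smoothSigma Gaussian blur scale in pixels (0 = hard edges).
#' @param seed integer seed controlling random blob geometry; ignored when
#'   \code{blobs} is supplied explicitly.
#' @return A \linkS4class{GrayImage} with values in [0, 1].
#' @examples
#' img <- generatePhantom(64, 64, smoothSigma = 0)
#' range(pixels(img))
#' @export
generatePhantom <- function(height = 128L, width = 128L, background = 0.2,
                            blobs = defaultBlobs(height, width),
                            smoothSigma = 1, seed = NULL) {
  stopifnot(height >= 8L, width >= 8L)
  if (background < 0 || background > 1)
    stop("background intensity must lie in [0, 1]")
  if (is.null(blobs)) {
    if (is.null(seed))
      stop("random blobs need a seed for reproducibility")
    blobs <- withSeed(seed, randomBlobs(height, width))
  }
  if (any(blobs$intensity < 0 | blobs$intensity > 1))
    stop("blob intensities must lie in [0, 1]")
  img <- matrix(background, height, width)
  rows <- row(img)
  cols <- col(img)
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    lim <- max(b$radiusRow, b$radiusCol)
    if (b$centerRow - lim < 0 || b$centerRow + lim > height + 1 ||
        b$centerCol - lim < 0 || b$centerCol + lim > width + 1)
      stop("blob ", i, " extends outside the image bounds")
    dr <- rows - b$centerRow
    dc <- cols - b$centerCol
    u <- cos(b$angle) * dr + sin(b$angle) * dc
    v <- -sin(b$angle) * dr + cos(b$angle) * dc
    img[(u / b$radiusRow)^2 + (v / b$radiusCol)^2 <= 1] <- b$intensity
  }
  if (smoothSigma > 0) img <- gaussianBlur(img, smoothSigma)
  GrayImage(img)
}

#' Add zero-mean Gaussian noise
#'
#' Adds an i.i.d. Gaussian field with standard deviation
#' \code{sigmaFraction} times the dynamic range, which is fixed at 1 for
#' normalised images: "25 percent Gaussian noise" means sigma = 0.25.  The
#' result is deliberately not clipped to [0, 1]; clipping would change the
#' noise distribution and invalidate the variance-based singular value
#' estimation in the WNNM core.
#'
#' @param image a \linkS4class{GrayImage} or numeric matrix.
#' @param sigmaFraction noise standard deviation as a fraction of the
#'   dynamic range; must be >= 0.
#' @param seed integer RNG seed; NULL draws from the current RNG stream.
#' @return A \linkS4class{GrayImage} of the same size.
#' @examples
#' img <- generatePhantom(32, 32)
#' noisy <- addGaussianNoise(img, 0.25, seed = 1)
#' sd(pixels(noisy) - pixels(img))
#' @export
addGaussianNoise <- function(image, sigmaFraction, seed = NULL) {
  if (sigmaFraction < 0) stop("sigmaFraction must be >= 0")
  px <- asPixels(image)
  if (sigmaFraction == 0) return(GrayImage(px))
  noise <- withSeed(seed,
    matrix(stats::rnorm(length(px), 0, sigmaFraction), nrow(px)))
  GrayImage(px + noise)
}
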