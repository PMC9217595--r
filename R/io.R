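#' Read a grayscale image
#'
#' PNG and TIFF intensities are mapped linearly to [0, 1] (multi-channel
#' files are averaged to grayscale); NIfTI volumes (.nii / .nii.gz, first
#' slice of a 3D volume) are returned on their native intensity scale.
#' NIfTI support needs the RNifti package.
#'
#' @param path file path; format chosen by extension.
#' @return A \linkS4class{GrayImage}.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("reading NIfTI needs the RNifti package")
      v <- RNifti::readNifti(path)
      a <- as.array(v)
      if (length(dim(a)) > 2L) a <- a[, , 1]
      a
    },
    stop("unsupported image format: .", ext))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  GrayImage(px)
}

#' Write a grayscale image
#'
#' PNG is written 8-bit and TIFF as 32-bit float; both formats store the
#' [0, 1] range, so values are clipped on write.  Unclipped out-of-range
#' intensities (noisy images) round-trip only through NIfTI, which stores
#' the raw matrix.
#'
#' @param image a \linkS4class{GrayImage} or numeric matrix.
#' @param path destination; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  px <- asPixels(image)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext,
    png = png::writePNG(pmin(pmax(px, 0), 1), path),
    tif = ,
    tiff = tiff::writeTIFF(pmin(pmax(px, 0), 1), path,
                           bits.per.sample = 32L),
    nii = {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("writing NIfTI needs the RNifti package")
      RNifti::writeNifti(RNifti::asNifti(px), path)
    },
    stop("unsupported image format: .", ext))
  invisible(path)
}
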