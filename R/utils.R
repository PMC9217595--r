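# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Half-up rounding (the convention of the printed clinical percentages;
# base::round rounds half to even).
roundHalfUp <- function(x, digits = 2L) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so exact .5 values in decimal survive
  # binary representation
  floor(x * scale + 0.5 + sign(x) * .Machine$double.eps * abs(x) * scale) /
    scale
}

# Separable Gaussian blur with reflected boundaries; sigma in pixels.
gaussianBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  blur1d <- function(v) {
    n <- length(v)
    padded <- c(v[radius:1], v, v[n:(n - radius + 1)])
    stats::filter(padded, k)[(radius + 1):(radius + n)]
  }
  out <- apply(mat, 2L, blur1d)
  t(apply(out, 1L, blur1d))
}

asPixels <- function(image) {
  if (is(image, "GrayImage")) image@.Data else as.matrix(image)
}
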