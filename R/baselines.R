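#' Perona-Malik anisotropic diffusion
#'
#' Explicit 4-neighbour nonlinear diffusion
#' \code{I <- I + dt * div(g(|grad I|) grad I)} with Neumann (reflecting)
#' boundaries.  The conduction function suppresses diffusion across strong
#' edges: rational \code{g(x) = 1 / (1 + (x/kappa)^2)} (default) or
#' exponential \code{g(x) = exp(-(x/kappa)^2)}.
#'
#' The scheme is written in divergence form with a shared conductance per
#' pixel pair, so the total intensity sum is conserved exactly (up to
#' floating point) at every step.
#'
#' @param image a \linkS4class{GrayImage} or numeric matrix.
#' @param iterations number of explicit time steps (>= 0).
#' @param kappa edge-stopping contrast parameter (> 0), intensity units.
#' @param dt time step; must satisfy 0 < dt <= 0.25 for 2D stability.
#' @param conduction "rational" or "exponential".
#' @return The diffused \linkS4class{GrayImage}.
#' @examples
#' img <- addGaussianNoise(generatePhantom(32, 32), 0.1, seed = 1)
#' peronaMalik(img, iterations = 10)
#' @export
peronaMalik <- function(image, iterations = 30L, kappa = 0.1, dt = 0.2,
                        conduction = c("rational", "exponential")) {
  conduction <- match.arg(conduction)
  if (iterations < 0) stop("iterations must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (dt <= 0 || dt > 0.25)
    stop("dt must lie in (0, 0.25] for explicit 2D stability")
  g <- switch(conduction,
              rational = function(x) 1 / (1 + (x / kappa)^2),
              exponential = function(x) exp(-(x / kappa)^2))
  px <- asPixels(image)
  h <- nrow(px); w <- ncol(px)
  for (i in seq_len(iterations)) {
    dN <- rbind(px[1, ], px[-h, ]) - px
    dS <- rbind(px[-1, ], px[h, ]) - px
    dW <- cbind(px[, 1], px[, -w]) - px
    dE <- cbind(px[, -1], px[, w]) - px
    px <- px + dt * (g(abs(dN)) * dN + g(abs(dS)) * dS +
                     g(abs(dW)) * dW + g(abs(dE)) * dE)
  }
  GrayImage(px)
}

#' Total variation (ROF) denoising
#'
#' Minimises \code{TV(u) + lambda/2 * ||u - n||^2} by Chambolle's dual
#' projection iteration.  Forward-difference gradient, backward-difference
#' divergence, Neumann boundaries; stops when the relative Frobenius change
#' of the primal iterate falls below \code{tol} or after \code{maxIters}
#' steps (with a warning in the latter case).
#'
#' @param image noisy \linkS4class{GrayImage} or numeric matrix.
#' @param lambda fidelity weight (> 0); smaller values smooth harder.  A
#'   practical operating point for noise level sigma is
#'   \code{lambda = 1 / (2 * sigma)}.
#' @param maxIters iteration cap (>= 1).
#' @param tol relative-change stopping tolerance (> 0).
#' @return The denoised \linkS4class{GrayImage}.
#' @examples
#' img <- addGaussianNoise(generatePhantom(32, 32), 0.25, seed = 1)
#' tvDenoise(img, lambda = 2)
#' @export
tvDenoise <- function(image, lambda, maxIters = 200L, tol = 1e-4) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (maxIters < 1) stop("maxIters must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  f <- asPixels(image)
  h <- nrow(f); w <- ncol(f)
  theta <- 1 / lambda
  tau <- 0.248  # < 1/8 ensures convergence of the dual iteration
  p1 <- matrix(0, h, w); p2 <- matrix(0, h, w)
  div_p <- function() p1 - rbind(0, p1[-h, ]) + p2 - cbind(0, p2[, -w])
  u <- f
  converged <- FALSE
  for (it in seq_len(maxIters)) {
    ut <- div_p() - f / theta
    g1 <- rbind(ut[-1, ], ut[h, ]) - ut
    g2 <- cbind(ut[, -1], ut[, w]) - ut
    ng <- sqrt(g1^2 + g2^2)
    p1 <- (p1 + tau * g1) / (1 + tau * ng)
    p2 <- (p2 + tau * g2) / (1 + tau * ng)
    uNew <- f - theta * div_p()
    if (sqrt(sum((uNew - u)^2)) / max(sqrt(sum(u^2)), 1e-12) < tol) {
      u <- uNew
      converged <- TRUE
      break
    }
    u <- uNew
  }
  if (!converged)
    warning("tvDenoise: not converged after ", maxIters,
            " iterations; returning current iterate")
  GrayImage(u)
}
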