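## Fluorescence-like rendering of fibril scenes.
##
## Coordinate convention: x runs along matrix columns, y along matrix rows,
## and orientations are measured from the x-axis towards increasing y in
## degrees.  Displayed with y pointing down (the usual image convention) a
## positive angle therefore appears as a clockwise tilt; the analysis stages
## use the identical frame, so orientations round-trip exactly.

## Rasterise one segment into `img` (modified in place semantics via return).
.drawSegment <- function(img, x0, y0, angleDeg, len, thick, amp) {
  size <- nrow(img)
  th <- .deg2rad(angleDeg)
  dx <- cos(th); dy <- sin(th)
  ext <- len / 2 + thick + 1
  i0 <- max(1L, floor(y0 - ext)); i1 <- min(size, ceiling(y0 + ext))
  j0 <- max(1L, floor(x0 - ext)); j1 <- min(size, ceiling(x0 + ext))
  if (i0 > i1 || j0 > j1) return(img)
  ys <- (i0:i1) - y0
  xs <- (j0:j1) - x0
  ## signed coordinates along (S) and across (Q) the segment axis
  S <- outer(ys * dy, xs * dx, `+`)
  Q <- outer(ys * dx, -xs * dy, `+`)
  covAlong <- pmin(1, pmax(0, len / 2 - abs(S) + 0.5))
  covAcross <- pmin(1, pmax(0, thick / 2 - abs(Q) + 0.5))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp * covAlong * covAcross
  img
}

## Separable Gaussian blur with finite support (kernel truncated at 3 sigma,
## renormalised), computed as banded-matrix products so a pixel is influenced
## only by pixels within the kernel reach -- the determinism contracts
## (noise-free parts identical, wound-outside pixel-identical) are then exact,
## not merely within FFT round-off.  Zero boundary: structures are not
## wrapped across image edges.
.gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- ceiling(3 * sigma)
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  n <- nrow(img)
  K <- matrix(0, n, n)
  for (d in -h:h) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + h + 1L]
  }
  K %*% img %*% K  # K is symmetric
}

## Half-width of the blur kernel's support, for locality accounting.
.blurReach <- function(sigma) if (sigma > 0) ceiling(3 * sigma) else 0

#' Render a fibril scene to a fluorescence-like intensity image
#'
#' Each segment is drawn as an anti-aliased straight line of the given
#' thickness and amplitude; segments sum additively, the result is convolved
#' with a Gaussian point-spread function, a constant background is added,
#' and (optionally) Gaussian read noise and/or Poisson shot noise are
#' applied under the scene's seed.  The returned image is clamped at zero,
#' and identical scene parameters and seed reproduce the identical image
#' bit for bit.
#'
#' @param scene a \linkS4class{FibrilScene}.
#'
#' @return a \code{size x size} numeric matrix of non-negative intensities.
#'
#' @examples
#' sc <- FibrilScene(size = 64,
#'                   segments = data.frame(x = 32, y = 32, angle = 30,
#'                                         length = 40, thickness = 3,
#'                                         amplitude = 1),
#'                   noiseSigma = 0, seed = 1)
#' range(renderScene(sc))
#'
#' @export
renderScene <- function(scene) {
  stopifnot(is(scene, "FibrilScene"))
  validObject(scene)
  size <- scene@size
  img <- matrix(0, size, size)
  seg <- scene@segments
  for (k in seq_len(nrow(seg)))
    img <- .drawSegment(img, seg$x[k], seg$y[k], seg$angle[k],
                        seg$length[k], seg$thickness[k], seg$amplitude[k])
  img <- .gaussianBlur(img, scene@psfSigma)
  img <- img + scene@background
  if (scene@noiseSigma > 0 || scene@poisson) {
    img <- withSeed(scene@seed, {
      if (scene@poisson) img <- matrix(stats::rpois(size^2, pmax(img, 0)),
                                       size, size)
      if (scene@noiseSigma > 0)
        img <- img + matrix(stats::rnorm(size^2, 0, scene@noiseSigma),
                            size, size)
      img
    })
  }
  pmax(img, 0)
}

#' Draw a random fibril scene from an orientation mixture
#'
#' Convenience generator used by the developmental and wound series:
#' fibril centres are uniform over the image, orientations are drawn from
#' \code{mixture} (see [sampleOrientations()]), lengths are normal around
#' \code{segmentLength} (sd 20\%, clamped to [6 px, 1.6 lengths]) and
#' amplitudes jitter
#' uniformly within 30\% of \code{amplitude}.
#'
#' @param mixture an \linkS4class{OrientationMixture}.
#' @param nFibrils number of fibril segments.
#' @param size image side in pixels.
#' @param segmentLength,segmentThickness,amplitude fibril rendering
#'   parameters (pixels, pixels, intensity units).
#' @param psfSigma,background,noiseSigma,poisson as in
#'   \linkS4class{FibrilScene}.
#' @param seed integer seed governing placement, orientations and noise.
#'
#' @return a list with elements \code{scene} (the
#'   \linkS4class{FibrilScene}) and \code{truth} (the ground-truth
#'   \linkS4class{OrientationSample} of segment orientations).
#'
#' @examples
#' sim <- simulateFibrilScene(OrientationMixture(mu = 45, kappa = 50),
#'                            nFibrils = 50, size = 128, seed = 1)
#' img <- renderScene(sim$scene)
#'
#' @export
simulateFibrilScene <- function(mixture, nFibrils, size = 512,
                                segmentLength = 60, segmentThickness = 2.5,
                                amplitude = 1, psfSigma = 1.2,
                                background = 0.05, noiseSigma = 0.02,
                                poisson = FALSE, seed) {
  stopifnot(is(mixture, "OrientationMixture"))
  nFibrils <- as.integer(nFibrils)
  ang <- if (nFibrils > 0)
    angles(sampleOrientations(mixture, nFibrils, seed = deriveSeed(seed, 1L)))
  else numeric()
  seg <- withSeed(deriveSeed(seed, 2L), {
    data.frame(
      x = stats::runif(nFibrils, 1, size),
      y = stats::runif(nFibrils, 1, size),
      angle = ang,
      length = pmin(1.6 * segmentLength,
                    pmax(6, stats::rnorm(nFibrils, segmentLength,
                                         0.2 * segmentLength))),
      thickness = rep(segmentThickness, nFibrils),
      amplitude = amplitude * stats::runif(nFibrils, 0.7, 1.3))
  })
  scene <- FibrilScene(size = size, segments = seg, psfSigma = psfSigma,
                       background = background, noiseSigma = noiseSigma,
                       poisson = poisson, seed = deriveSeed(seed, 3L))
  list(scene = scene, truth = OrientationSample(angles = ang))
}
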