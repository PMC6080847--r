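## Axial von Mises sampling.
##
## Orientations are axial (period 180 deg), so sampling is performed on the
## doubled angle: draw phi ~ vonMises(2 mu, kappa) on the circle and halve
## back, theta = (phi / 2) mod 180.  kappa = 0 reduces to the uniform
## distribution on [0, 180).

## von Mises sampler (Best & Fisher 1979 rejection scheme), angles in
## radians on [0, 2 pi).  Vectorised in batches; no package in this stack
## provides circular distributions, so this primitive is implemented here.
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric())
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric()
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / 0.55) + 10L
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok]))))
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' Sample fibril orientations from an axial von Mises mixture
#'
#' Draws \code{n} axial orientations from an
#' \linkS4class{OrientationMixture}.  Each draw picks a mixture component by
#' weight, samples the doubled angle from a von Mises distribution with mean
#' \code{2 mu} and concentration \code{kappa}, and halves back into
#' [0, 180).  A component with \code{kappa = 0} yields orientations uniform
#' on [0, 180).
#'
#' @param mixture an \linkS4class{OrientationMixture}.
#' @param n number of orientations to draw (>= 1).
#' @param seed integer seed; identical \code{(mixture, n, seed)} reproduce
#'   the identical sample.
#'
#' @return an \linkS4class{OrientationSample} of \code{n} unweighted angles.
#'
#' @examples
#' mix <- OrientationMixture(mu = c(45, 135), kappa = 20)
#' s <- sampleOrientations(mix, 500, seed = 1)
#' alignmentIndex(s)
#'
#' @export
sampleOrientations <- function(mixture, n, seed) {
  stopifnot(is(mixture, "OrientationMixture"))
  validObject(mixture)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  ang <- withSeed(seed, {
    comp <- sample.int(length(mixture@mu), n, replace = TRUE,
                       prob = mixture@weight)
    out <- numeric(n)
    for (k in seq_along(mixture@mu)) {
      idx <- which(comp == k)
      if (!length(idx)) next
      kap <- mixture@kappa[k]
      if (is.infinite(kap)) {
        out[idx] <- mixture@mu[k]
      } else {
        phi <- rvonmises(length(idx), .deg2rad(2 * mixture@mu[k]), kap)
        out[idx] <- (.rad2deg(phi) / 2) %% 180
      }
    }
    out
  })
  OrientationSample(angles = ang)
}
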