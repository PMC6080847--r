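# Shared fixtures and independent oracles, built in code.

# Rayleigh test of circular uniformity on the DOUBLED angles (the standard
# axial-uniformity oracle); returns the approximate p value.
rayleighP <- function(thetaDeg) {
  phi <- 2 * thetaDeg * pi / 180
  n <- length(phi)
  R <- sqrt(sum(cos(phi))^2 + sum(sin(phi))^2) / n
  Z <- n * R^2
  exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
}

# Direct AI formula on raw angles (independent of the package's S4 path).
aiOracle <- function(thetaDeg, ref = NULL) {
  if (is.null(ref)) {
    ref <- atan2(sum(sin(2 * thetaDeg * pi / 180)),
                 sum(cos(2 * thetaDeg * pi / 180))) / 2 * 180 / pi
  }
  abs(mean(cos(2 * (thetaDeg - ref) * pi / 180)))
}

# Dominant-range AI oracle: restrict ground-truth angles to the range
# ([0,90) or [90,180)) holding the larger share, then apply the AI formula.
aiOracleDominant <- function(thetaDeg) {
  low <- thetaDeg < 90
  keep <- if (sum(low) >= sum(!low)) thetaDeg[low] else thetaDeg[!low]
  aiOracle(keep)
}

# Single-family test image with known ground truth.
familyImage <- function(mu, kappa, n = 150, size = 256, seed = 1,
                        noiseSigma = 0.02) {
  sim <- simulateFibrilScene(OrientationMixture(mu = mu, kappa = kappa),
                             nFibrils = n, size = size,
                             noiseSigma = noiseSigma, seed = seed)
  list(image = renderScene(sim$scene), truth = angles(sim$truth))
}

# Bilinear rotation of image content by `deg` in the package's (x = column,
# y = row) frame, about the image centre; pixels mapped from outside are 0.
rotateImage <- function(img, deg) {
  n <- nrow(img)
  c0 <- (n + 1) / 2
  th <- -deg * pi / 180  # inverse mapping
  xs <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - c0, n, n)
  xsrc <- cos(th) * xs - sin(th) * ys + c0
  ysrc <- sin(th) * xs + cos(th) * ys + c0
  j0 <- floor(xsrc); i0 <- floor(ysrc)
  fx <- xsrc - j0; fy <- ysrc - i0
  ok <- j0 >= 1 & j0 < n & i0 >= 1 & i0 < n
  at <- function(i, j) (j - 1) * n + i
  v <- numeric(n * n)
  v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[at(i0[ok], j0[ok])] +
    fx[ok] * (1 - fy[ok]) * img[at(i0[ok], j0[ok] + 1)] +
    (1 - fx[ok]) * fy[ok] * img[at(i0[ok] + 1, j0[ok])] +
    fx[ok] * fy[ok] * img[at(i0[ok] + 1, j0[ok] + 1)]
  matrix(v, n, n)
}

# Central crop (removes rotation padding corners).
centralCrop <- function(img, frac = 0.56) {
  n <- nrow(img)
  k <- round(n * (1 - frac) / 2)
  img[(k + 1):(n - k), (k + 1):(n - k)]
}

# Mean orientation of the background-subtracted Fourier histogram of an
# image (the orientation estimator used downstream of the spectrum).
fourierTheta <- function(img, params = DirectionalityParams()) {
  as.numeric(circularMeanOrientation(
    subtractBackground(angularHistogram(powerSpectrum(img, params), params))))
}

# Central square crop of side `keep`.
squareCrop <- function(img, keep) {
  k <- floor((nrow(img) - keep) / 2)
  img[(k + 1):(k + keep), (k + 1):(k + keep)]
}

# Histogram peak location in degrees.
histPeak <- function(h) binCenters(h)[which.max(binValues(h))]

# Circular (axial, period 180) absolute difference in degrees.
axialDiff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
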