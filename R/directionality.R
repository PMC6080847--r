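## The Fourier power-spectrum directionality stage.
##
## An elongated structure at real-space orientation theta concentrates its
## spectral energy along the line perpendicular to theta in the frequency
## plane.  The angular histogram therefore applies a 90 degree rotation
## when mapping frequency-plane orientation to fibril orientation, so every
## angle downstream of this stage is a real-space fibril orientation.

#' Centered 2D power spectrum of an image
#'
#' Subtracts the image mean, applies the window, pads to a square, Fourier
#' transforms and returns the squared magnitude with zero frequency at the
#' centre (index \code{floor(n/2) + 1}).  The spectrum is scaled by
#' \code{1/n_pixels} so that Parseval's identity holds:
#' \code{sum(spectrum) == sum(windowed_image^2)}.
#'
#' @param image 2D numeric matrix, finite-valued.
#' @param params a \linkS4class{DirectionalityParams}.
#'
#' @return a square numeric matrix of non-negative spectral power.
#'
#' @examples
#' img <- matrix(cos(2 * pi * 0.2 * col(matrix(0, 64, 64))), 64, 64)
#' spec <- powerSpectrum(img, DirectionalityParams())
#'
#' @seealso [angularHistogram()]
#' @export
powerSpectrum <- function(image, params = DirectionalityParams()) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2D numeric matrix")
  if (!all(is.finite(image))) stop("image must be finite-valued")
  validObject(params)
  x <- image - mean(image)
  if (params@window == "hann")
    x <- x * outer(hannWindow(nrow(x)), hannWindow(ncol(x)))
  n <- max(dim(x))
  if (params@padPow2) n <- stats::nextn(n, 2)
  padded <- matrix(0, n, n)
  padded[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  P <- Mod(stats::fft(padded))^2 / length(padded)
  ord <- fftshiftIndex(n)
  P[ord, ord]
}

#' Angular orientation histogram of a power spectrum
#'
#' Accumulates the spectral energy within the radial band
#' \code{[fmin, fmax]} (fractions of Nyquist) into angular bins by the
#' orientation of each frequency-plane point, applying the 90 degree
#' rotation between frequency-space and real-space orientation, and folding
#' opposite half-planes together (axial symmetry) into [0, 180).  Each
#' frequency pixel contributes to the single bin containing its orientation
#' (no interpolation); per-bin energy is normalised by the number of
#' frequency-plane pixels in the bin (rescaled by the mean count) to remove
#' the anisotropy of the integer frequency lattice, whose axis lines
#' otherwise inflate the bins at 0 and 90 degrees.
#'
#' @param spectrum a centred non-negative spectrum from [powerSpectrum()].
#' @param params a \linkS4class{DirectionalityParams}.
#'
#' @return an \linkS4class{OrientationHistogram} (provenance
#'   \code{"fourier"}) in real-space fibril coordinates.
#'
#' @examples
#' ## stripes running vertically (image varies along x) -> fibrils at 90 deg
#' img <- matrix(cos(2 * pi * 0.2 * col(matrix(0, 128, 128))), 128, 128)
#' h <- angularHistogram(powerSpectrum(img), DirectionalityParams())
#' binCenters(h)[which.max(binValues(h))]
#'
#' @export
angularHistogram <- function(spectrum, params = DirectionalityParams()) {
  if (!is.matrix(spectrum) || nrow(spectrum) != ncol(spectrum))
    stop("spectrum must be a square matrix (see powerSpectrum)")
  if (any(spectrum < 0)) stop("spectrum must be non-negative")
  validObject(params)
  n <- nrow(spectrum)
  kv <- frequencyValues(n)
  KX <- matrix(kv, n, n, byrow = TRUE)
  KY <- matrix(kv, n, n)
  r <- sqrt(KX^2 + KY^2) / 0.5  # fraction of Nyquist
  sel <- r >= params@fmin & r <= params@fmax
  if (!any(sel))
    stop("empty radial band: no frequency pixels between fmin and fmax")
  theta <- (.rad2deg(atan2(KY[sel], KX[sel])) + 90) %% 180
  bins <- params@bins
  bw <- 180 / bins
  idx <- pmin(bins, 1L + as.integer(floor(theta / bw)))
  energy <- counts <- numeric(bins)
  agg <- rowsum(spectrum[sel], idx)
  energy[as.integer(rownames(agg))] <- agg
  cnt <- tabulate(idx, nbins = bins)
  vals <- ifelse(cnt > 0, energy / cnt, 0) * mean(cnt)
  OrientationHistogram(centers = (seq_len(bins) - 0.5) * bw, values = vals,
                       normalized = FALSE, provenance = "fourier",
                       degenerate = FALSE)
}

#' Bin ground-truth angles into an orientation histogram
#'
#' Simple binning of an \linkS4class{OrientationSample} with unit (or the
#' sample's) weight per measurement; the oracle path mirroring the Fourier
#' histogram.  Angles must already lie in [0, 180) (wrap axial angles
#' first).
#'
#' @param sample an \linkS4class{OrientationSample} or numeric vector of
#'   angles in degrees.
#' @param bins number of bins over [0, 180).
#'
#' @return an \linkS4class{OrientationHistogram} (provenance
#'   \code{"ground_truth"}).
#'
#' @examples
#' h <- histogramFromAngles(c(45, 45, 45), bins = 90)
#' sum(binValues(h) > 0)  # a single occupied bin
#'
#' @export
histogramFromAngles <- function(sample, bins = 90L) {
  if (is.numeric(sample)) sample <- OrientationSample(angles = sample)
  stopifnot(is(sample, "OrientationSample"))
  validObject(sample)
  bins <- as.integer(bins)
  if (bins < 8L) stop("bins must be >= 8")
  th <- angles(sample)
  w <- weights(sample)
  bw <- 180 / bins
  vals <- numeric(bins)
  if (length(th)) {
    idx <- pmin(bins, 1L + as.integer(floor(th / bw)))
    agg <- rowsum(w, idx)
    vals[as.integer(rownames(agg))] <- agg
  }
  OrientationHistogram(centers = (seq_len(bins) - 0.5) * bw, values = vals,
                       normalized = FALSE, provenance = "ground_truth",
                       degenerate = FALSE)
}

#' Normalise an orientation histogram to unit mass
#'
#' @param hist an \linkS4class{OrientationHistogram}.
#' @return the histogram with values summing to 1 (unchanged, flagged
#'   degenerate, if the total mass is zero).
#' @export
normalizeHistogram <- function(hist) {
  stopifnot(is(hist, "OrientationHistogram"))
  tot <- sum(binValues(hist))
  if (tot <= 0) {
    hist@degenerate <- TRUE
    return(hist)
  }
  OrientationHistogram(centers = binCenters(hist),
                       values = binValues(hist) / tot, normalized = TRUE,
                       provenance = provenance(hist),
                       degenerate = isDegenerate(hist))
}
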