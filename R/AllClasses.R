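## Central S4 containers.  All angles in the package are axial orientations:
## degrees, measured from the image x-axis (column direction), defined modulo
## 180 and stored in the half-open range [0, 180).

.checkAngles <- function(a, what = "angles") {
  if (length(a) && (!is.numeric(a) || anyNA(a)))
    return(sprintf("%s must be numeric and non-missing", what))
  if (length(a) && (any(a < 0) || any(a >= 180)))
    return(sprintf("%s must lie in [0, 180); wrap axial angles first", what))
  NULL
}

#' Axial von Mises orientation mixture
#'
#' A mixture of axial von Mises components describing a distribution of
#' fibril orientations.  Each component has a mean orientation \code{mu}
#' (degrees in [0, 180)), a non-negative concentration \code{kappa}
#' (\code{kappa = 0} is uniform on [0, 180)) and a non-negative
#' \code{weight}.  Sampling doubles the angles (period 360 degrees for the
#' doubled angle, i.e. period 180 for the orientation), draws from a von
#' Mises distribution and halves back, so \code{mu} and \code{mu + 180} are
#' the same orientation.
#'
#' @slot mu numeric, component mean orientations in degrees, [0, 180).
#' @slot kappa numeric, non-negative concentrations (on the doubled angle).
#' @slot weight numeric, mixture weights, normalised to sum to 1.
#'
#' @param mu,kappa,weight component parameters, recycled to a common length.
#' @return \code{OrientationMixture()} returns an OrientationMixture object.
#'
#' @examples
#' ## two orthogonal fibril families, one per split range
#' OrientationMixture(mu = c(45, 135), kappa = 20)
#' ## an isotropic (entirely random) orientation field
#' OrientationMixture(mu = 0, kappa = 0)
#'
#' @aliases OrientationMixture
#' @export OrientationMixture
#' @exportClass OrientationMixture
OrientationMixture <- setClass("OrientationMixture",
  slots = c(mu = "numeric", kappa = "numeric", weight = "numeric"),
  validity = function(object) {
    n <- length(object@mu)
    if (n < 1L) return("mixture must have at least one component")
    if (length(object@kappa) != n || length(object@weight) != n)
      return("mu, kappa and weight must have equal length")
    msg <- .checkAngles(object@mu, "component means (mu)")
    if (!is.null(msg)) return(msg)
    if (anyNA(object@kappa) || any(object@kappa < 0) ||
        any(!is.finite(object@kappa) & object@kappa != Inf))
      return("kappa must be finite and non-negative")
    if (anyNA(object@weight) || any(object@weight < 0))
      return("weights must be non-negative")
    if (sum(object@weight) <= 0) return("weights must not all be zero")
    if (abs(sum(object@weight) - 1) > 1e-8)
      return("weights must be normalised to sum to 1")
    TRUE
  })

#' @rdname OrientationMixture-class
#' @usage OrientationMixture(mu, kappa = 0, weight = 1)
setMethod("initialize", "OrientationMixture",
  function(.Object, mu = numeric(), kappa = 0, weight = 1, ...) {
    n <- max(length(mu), length(kappa), length(weight))
    if (length(mu)) {
      mu <- rep_len(as.numeric(mu), n) %% 180
      kappa <- rep_len(as.numeric(kappa), n)
      weight <- rep_len(as.numeric(weight), n)
      if (sum(weight) > 0) weight <- weight / sum(weight)
    }
    callNextMethod(.Object, mu = mu, kappa = kappa, weight = weight, ...)
  })

#' Sample of axial angular measurements
#'
#' A list of angular measurements \eqn{\theta_i} (axial, degrees in
#' [0, 180)) with optional non-negative weights; the domain of the Alignment
#' Index formula.
#'
#' @slot angles numeric, degrees in [0, 180).
#' @slot weights numeric, same length as \code{angles}, or length zero for
#'   unit weights.
#'
#' @param angles,weights see slots.
#' @return \code{OrientationSample()} returns an OrientationSample.
#'
#' @examples
#' s <- OrientationSample(c(10, 30))
#' circularMeanOrientation(s)
#' alignmentIndex(s)
#'
#' @aliases OrientationSample angles,OrientationSample-method
#'   weights.OrientationSample length,OrientationSample-method
#' @export OrientationSample
#' @exportClass OrientationSample
OrientationSample <- setClass("OrientationSample",
  slots = c(angles = "numeric", weights = "numeric"),
  prototype = list(angles = numeric(), weights = numeric()),
  validity = function(object) {
    msg <- .checkAngles(object@angles)
    if (!is.null(msg)) return(msg)
    w <- object@weights
    if (length(w) && length(w) != length(object@angles))
      return("weights must be empty or match angles in length")
    if (length(w) && (anyNA(w) || any(w < 0)))
      return("weights must be non-negative")
    TRUE
  })

#' @export
setMethod("angles", "OrientationSample", function(x) x@angles)

#' @importFrom stats weights
#' @export
weights.OrientationSample <- function(object, ...) {
  if (length(object@weights)) object@weights
  else rep(1, length(object@angles))
}

setMethod("length", "OrientationSample", function(x) length(x@angles))

setMethod("show", "OrientationSample", function(object) {
  cat(sprintf("OrientationSample with %d measurement(s)%s\n",
              length(object@angles),
              if (length(object@weights)) " (weighted)" else ""))
  if (length(object@angles)) {
    th <- circularMeanOrientation(object)
    cat(sprintf("  theta_th = %.2f deg, AI = %.4f\n", th,
                alignmentIndex(object, theta = th)))
  }
})

#' Binned angular orientation distribution
#'
#' An angular histogram over [0, 180) with uniform bin width, produced
#' either from the Fourier power spectrum of an image
#' ([angularHistogram()], provenance \code{"fourier"}) or by binning
#' ground-truth angles ([histogramFromAngles()], provenance
#' \code{"ground_truth"}).
#'
#' @slot centers numeric, strictly increasing uniform bin centres, degrees
#'   in [0, 180).
#' @slot values numeric, non-negative bin weights.
#' @slot normalized logical; when TRUE the values sum to 1.
#' @slot provenance character, \code{"fourier"} or \code{"ground_truth"}.
#' @slot degenerate logical; TRUE when background subtraction removed all
#'   signal (flat input histogram).
#'
#' @param centers,values,normalized,provenance,degenerate see slots.
#' @return \code{OrientationHistogram()} returns an OrientationHistogram.
#'
#' @aliases OrientationHistogram binCenters binValues binWidth provenance
#'   isDegenerate binCenters,OrientationHistogram-method
#'   binValues,OrientationHistogram-method
#'   binWidth,OrientationHistogram-method
#'   provenance,OrientationHistogram-method
#'   isDegenerate,OrientationHistogram-method
#' @export OrientationHistogram
#' @exportClass OrientationHistogram
OrientationHistogram <- setClass("OrientationHistogram",
  slots = c(centers = "numeric", values = "numeric", normalized = "logical",
            provenance = "character", degenerate = "logical"),
  prototype = list(normalized = FALSE, provenance = "fourier",
                   degenerate = FALSE),
  validity = function(object) {
    if (length(object@centers) < 2L) return("histogram needs >= 2 bins")
    if (length(object@values) != length(object@centers))
      return("centers and values must have equal length")
    msg <- .checkAngles(object@centers, "bin centers")
    if (!is.null(msg)) return(msg)
    d <- diff(object@centers)
    if (any(d <= 0)) return("bin centers must be strictly increasing")
    if (diff(range(d)) > 1e-8 * max(d)) return("bin width must be uniform")
    if (anyNA(object@values) || any(object@values < 0))
      return("bin values must be non-negative")
    if (isTRUE(object@normalized) && sum(object@values) > 0 &&
        abs(sum(object@values) - 1) > 1e-6)
      return("normalized histogram values must sum to 1")
    TRUE
  })

#' @export
setMethod("binCenters", "OrientationHistogram", function(x) x@centers)
#' @export
setMethod("binValues", "OrientationHistogram", function(x) x@values)
#' @export
setMethod("binWidth", "OrientationHistogram",
          function(x) x@centers[2L] - x@centers[1L])
#' @export
setMethod("provenance", "OrientationHistogram", function(x) x@provenance)
#' @export
setMethod("isDegenerate", "OrientationHistogram", function(x) x@degenerate)

setMethod("show", "OrientationHistogram", function(object) {
  cat(sprintf(
    "OrientationHistogram: %d bins of %.3g deg [%s%s%s], total mass %.4g\n",
    length(object@centers), binWidth(object), object@provenance,
    if (object@normalized) ", normalized" else "",
    if (object@degenerate) ", degenerate" else "",
    sum(object@values)))
})

#' Parameters of the Fourier directionality analysis
#'
#' Controls the power-spectrum orientation histogram: number of angular
#' bins over [0, 180), window function, the radial frequency band analysed
#' (as a fraction of the Nyquist frequency), and padding.
#'
#' Defaults: 90 bins of 2 degrees, Hann window (suppresses edge-induced
#' axis artifacts), radial band 0.02--0.9 of Nyquist (excludes the DC /
#' low-frequency background and the anisotropic spectrum corners), pad to
#' square.
#'
#' @slot bins integer, number of angular bins (>= 8; use an even count so
#'   bin edges align with the 90 degree range split).
#' @slot window character, \code{"hann"} or \code{"none"}.
#' @slot fmin,fmax numeric, radial band limits as fractions of Nyquist,
#'   0 <= fmin < fmax <= 1.
#' @slot padPow2 logical; when TRUE pad the square side up to the next
#'   highly-composite size accepted by the FFT.
#'
#' @param bins,window,fmin,fmax,padPow2 see slots.
#' @return \code{DirectionalityParams()} returns a DirectionalityParams.
#'
#' @examples
#' DirectionalityParams()
#' DirectionalityParams(bins = 180, fmax = 0.8)
#'
#' @aliases DirectionalityParams
#' @export DirectionalityParams
#' @exportClass DirectionalityParams
DirectionalityParams <- setClass("DirectionalityParams",
  slots = c(bins = "integer", window = "character", fmin = "numeric",
            fmax = "numeric", padPow2 = "logical"),
  prototype = list(bins = 90L, window = "hann", fmin = 0.02, fmax = 0.9,
                   padPow2 = FALSE),
  validity = function(object) {
    if (length(object@bins) != 1L || is.na(object@bins) || object@bins < 8L)
      return("bins must be a single integer >= 8")
    if (!object@window %in% c("hann", "none"))
      return("window must be 'hann' or 'none'")
    if (object@fmin < 0 || object@fmin >= object@fmax || object@fmax > 1)
      return("radial band must satisfy 0 <= fmin < fmax <= 1")
    TRUE
  })

setMethod("initialize", "DirectionalityParams",
  function(.Object, bins = 90L, ...) {
    callNextMethod(.Object, bins = as.integer(bins), ...)
  })

setMethod("show", "DirectionalityParams", function(object) {
  cat(sprintf(
    "DirectionalityParams: %d bins (%.3g deg), %s window, band %.3g-%.3g Nyquist%s\n",
    object@bins, 180 / object@bins, object@window, object@fmin, object@fmax,
    if (object@padPow2) ", pad to power of two" else ""))
})

#' Ground-truth description of a synthetic fibril image
#'
#' A scene is a set of straight fibril segments with known orientations
#' plus rendering parameters (point-spread blur, background, noise).
#' [renderScene()] turns a scene into a non-negative intensity image;
#' identical scene and seed reproduce the identical image bit for bit.
#'
#' @slot size integer, image side length in pixels (square image).
#' @slot segments data.frame with columns \code{x}, \code{y} (centre,
#'   pixels), \code{angle} (degrees in [0, 180)), \code{length},
#'   \code{thickness} (pixels) and \code{amplitude} (intensity units).
#' @slot psfSigma numeric, Gaussian point-spread sigma in pixels.
#' @slot background numeric, constant background intensity.
#' @slot noiseSigma numeric, Gaussian read-noise sigma (0 = none).
#' @slot poisson logical, apply Poisson (shot) noise.
#' @slot seed integer seed for the noise draw (NA = noise forbidden).
#'
#' @param size,segments,psfSigma,background,noiseSigma,poisson,seed see
#'   slots.
#' @return \code{FibrilScene()} returns a FibrilScene.
#'
#' @examples
#' sc <- FibrilScene(size = 64,
#'                   segments = data.frame(x = 32, y = 32, angle = 0,
#'                                         length = 40, thickness = 3,
#'                                         amplitude = 1),
#'                   noiseSigma = 0, seed = 1)
#' img <- renderScene(sc)
#'
#' @aliases FibrilScene
#' @export FibrilScene
#' @exportClass FibrilScene
FibrilScene <- setClass("FibrilScene",
  slots = c(size = "integer", segments = "data.frame", psfSigma = "numeric",
            background = "numeric", noiseSigma = "numeric",
            poisson = "logical", seed = "numeric"),
  prototype = list(size = 512L, psfSigma = 1.2, background = 0.05,
                   noiseSigma = 0.02, poisson = FALSE, seed = NA_real_),
  validity = function(object) {
    if (length(object@size) != 1L || is.na(object@size) || object@size < 8L)
      return("image size must be a single integer >= 8 pixels")
    seg <- object@segments
    need <- c("x", "y", "angle", "length", "thickness", "amplitude")
    if (!all(need %in% names(seg)))
      return(paste("segments must have columns:", paste(need, collapse = ", ")))
    if (nrow(seg)) {
      msg <- .checkAngles(seg$angle, "segment orientations")
      if (!is.null(msg)) return(msg)
      if (any(seg$length <= 0) || any(seg$thickness <= 0))
        return("segment length and thickness must be positive")
      if (any(seg$amplitude < 0)) return("segment amplitude must be >= 0")
    }
    if (object@psfSigma < 0) return("psfSigma must be >= 0")
    if (object@background < 0) return("background must be >= 0")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if ((object@noiseSigma > 0 || object@poisson) && is.na(object@seed))
      return("a seed is required when the scene has noise")
    TRUE
  })

setMethod("initialize", "FibrilScene",
  function(.Object, size = 512L, segments = NULL, ...) {
    if (is.null(segments))
      segments <- data.frame(x = numeric(), y = numeric(), angle = numeric(),
                             length = numeric(), thickness = numeric(),
                             amplitude = numeric())
    callNextMethod(.Object, size = as.integer(size), segments = segments, ...)
  })

setMethod("show", "FibrilScene", function(object) {
  cat(sprintf(
    "FibrilScene: %d x %d px, %d segment(s), psf %.3g px, background %.3g, %s\n",
    object@size, object@size, nrow(object@segments), object@psfSigma,
    object@background,
    if (object@noiseSigma > 0 || object@poisson)
      sprintf("noise (gaussian %.3g%s, seed %g)", object@noiseSigma,
              if (object@poisson) " + poisson" else "", object@seed)
    else "no noise"))
})

#' Wound scenario for the wound-repair image series
#'
#' Describes a composite image: an orthogonal-lattice fibril field outside
#' a circular wound, and a wound disk whose fibril density (as a fraction of
#' the outside areal density) and orientation distribution vary over a
#' simulated post-injury timecourse.  See [makeWoundSeries()].
#'
#' @slot size integer, image side in pixels.
#' @slot outsideMixture an \linkS4class{OrientationMixture} for the
#'   unwounded lattice (default two orthogonal families at 45/135 degrees).
#' @slot nFibrils integer, fibril count of the unwounded lattice.
#' @slot segmentLength,segmentThickness,amplitude rendering parameters of
#'   individual fibrils (pixels, pixels, intensity).
#' @slot psfSigma,background,noiseSigma as in \linkS4class{FibrilScene}.
#' @slot woundCenter numeric length 2, wound centre (x, y) in pixels.
#' @slot woundRadius numeric, wound radius in pixels (> 0).
#' @slot insideMixture an \linkS4class{OrientationMixture} for fibrils
#'   deposited inside the wound.
#' @slot densityFraction numeric in [0, 1], inside-wound fibril density as a
#'   fraction of the outside density.
#' @slot label character timepoint label.
#'
#' @param ... slot values replacing the defaults.
#' @return \code{WoundScenario()} returns a WoundScenario.
#'
#' @aliases WoundScenario
#' @export WoundScenario
#' @exportClass WoundScenario
WoundScenario <- setClass("WoundScenario",
  slots = c(size = "integer", outsideMixture = "OrientationMixture",
            nFibrils = "integer", segmentLength = "numeric",
            segmentThickness = "numeric", amplitude = "numeric",
            psfSigma = "numeric", background = "numeric",
            noiseSigma = "numeric", woundCenter = "numeric",
            woundRadius = "numeric", insideMixture = "OrientationMixture",
            densityFraction = "numeric", label = "character"),
  validity = function(object) {
    if (object@woundRadius <= 0) return("wound radius must be > 0")
    r <- object@woundRadius
    ctr <- object@woundCenter
    if (length(ctr) != 2L || anyNA(ctr))
      return("woundCenter must be numeric length 2")
    if (any(ctr - r < 1) || any(ctr + r > object@size))
      return("wound disk must lie within the image bounds")
    if (object@densityFraction < 0 || object@densityFraction > 1)
      return("densityFraction must lie in [0, 1]")
    if (object@nFibrils < 0) return("nFibrils must be >= 0")
    TRUE
  })

setMethod("initialize", "WoundScenario",
  function(.Object, size = 512L, nFibrils = 600L,
           outsideMixture = OrientationMixture(mu = c(45, 135), kappa = 20),
           insideMixture = OrientationMixture(mu = 0, kappa = 0),
           segmentLength = 60, segmentThickness = 2.5, amplitude = 1,
           psfSigma = 1.2, background = 0.05, noiseSigma = 0.02,
           woundCenter = NULL, woundRadius = NULL,
           densityFraction = 0, label = "wound", ...) {
    size <- as.integer(size)
    if (is.null(woundRadius)) woundRadius <- size / 4
    if (is.null(woundCenter)) woundCenter <- c(size, size) / 2
    callNextMethod(.Object, size = size, nFibrils = as.integer(nFibrils),
                   outsideMixture = outsideMixture,
                   insideMixture = insideMixture,
                   segmentLength = segmentLength,
                   segmentThickness = segmentThickness, amplitude = amplitude,
                   psfSigma = psfSigma, background = background,
                   noiseSigma = noiseSigma, woundCenter = woundCenter,
                   woundRadius = woundRadius,
                   densityFraction = densityFraction, label = label, ...)
  })

setMethod("show", "WoundScenario", function(object) {
  cat(sprintf(
    "WoundScenario '%s': %d px image, %d lattice fibrils, wound r=%.4g px at (%.4g, %.4g), inside density %.3g\n",
    object@label, object@size, object@nFibrils, object@woundRadius,
    object@woundCenter[1], object@woundCenter[2], object@densityFraction))
})

#' Per-image Alignment Index result
#'
#' Per-range and combined Alignment Index values produced by
#' [analyzeImage()]: the AI and mean orientation \eqn{\theta_{th}} of the
#' 0--90 and 90--180 degree ranges of the background-subtracted angular
#' histogram, the histogram mass of each range, and the mass-weighted
#' combined AI.  A range with no mass is degenerate: its AI is 0 and its
#' \eqn{\theta_{th}} is NA.
#'
#' @slot aiLow,aiHigh numeric AI in [0, 1] for the 0--90 / 90--180 range.
#' @slot thetaLow,thetaHigh numeric mean orientation per range (degrees,
#'   NA when degenerate).
#' @slot massLow,massHigh numeric total histogram weight per range.
#' @slot aiCombined numeric, mass-weighted mean of the two range AIs.
#' @slot degenerateLow,degenerateHigh logical per-range degeneracy flags.
#'
#' @param x an AIResult.
#' @aliases AIResult aiLow aiHigh aiCombined aiDominant thetaLow thetaHigh
#'   rangeMasses aiLow,AIResult-method aiHigh,AIResult-method
#'   aiCombined,AIResult-method aiDominant,AIResult-method
#'   thetaLow,AIResult-method thetaHigh,AIResult-method
#'   rangeMasses,AIResult-method as.data.frame.AIResult
#' @exportClass AIResult
setClass("AIResult",
  slots = c(aiLow = "numeric", aiHigh = "numeric", thetaLow = "numeric",
            thetaHigh = "numeric", massLow = "numeric", massHigh = "numeric",
            aiCombined = "numeric", degenerateLow = "logical",
            degenerateHigh = "logical"),
  validity = function(object) {
    ai <- c(object@aiLow, object@aiHigh, object@aiCombined)
    if (anyNA(ai) || any(ai < -1e-12) || any(ai > 1 + 1e-12))
      return("AI values must lie in [0, 1]")
    if (object@massLow < 0 || object@massHigh < 0)
      return("range masses must be >= 0")
    TRUE
  })

#' @export
setMethod("aiLow", "AIResult", function(x) x@aiLow)
#' @export
setMethod("aiHigh", "AIResult", function(x) x@aiHigh)
#' @export
setMethod("aiCombined", "AIResult", function(x) x@aiCombined)
#' @export
setMethod("thetaLow", "AIResult", function(x) x@thetaLow)
#' @export
setMethod("thetaHigh", "AIResult", function(x) x@thetaHigh)
#' @export
setMethod("rangeMasses", "AIResult",
          function(x) c(low = x@massLow, high = x@massHigh))

#' @export
setMethod("aiDominant", "AIResult", function(x) {
  if (x@massLow >= x@massHigh) x@aiLow else x@aiHigh
})

#' @export
as.data.frame.AIResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(ai_low = x@aiLow, ai_high = x@aiHigh,
             theta_th_low = x@thetaLow, theta_th_high = x@thetaHigh,
             mass_low = x@massLow, mass_high = x@massHigh,
             ai_combined = x@aiCombined,
             degenerate_low = x@degenerateLow,
             degenerate_high = x@degenerateHigh,
             row.names = row.names)
}

setMethod("show", "AIResult", function(object) {
  fmt <- function(ai, th, m, d)
    sprintf("AI %.4f, theta_th %s deg, mass %.4g%s", ai,
            ifelse(is.na(th), "NA", sprintf("%.2f", th)), m,
            if (d) " [degenerate]" else "")
  cat("AIResult\n")
  cat("  0-90 deg  :", fmt(object@aiLow, object@thetaLow, object@massLow,
                           object@degenerateLow), "\n")
  cat("  90-180 deg:", fmt(object@aiHigh, object@thetaHigh, object@massHigh,
                           object@degenerateHigh), "\n")
  cat(sprintf("  combined  : AI %.4f (mass-weighted)\n", object@aiCombined))
})
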