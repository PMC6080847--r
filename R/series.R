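## Synthetic developmental and wound-repair image series.
##
## The presets emulate the sub-epidermal collagen-I patterns seen in larval
## zebrafish skin: sparse randomly-oriented wisps shortly after the first
## deposition, a loosely orthogonal cross-hatch as remodelling begins, and a
## tight two-family orthogonal lattice once the plywood architecture is
## mature.  The wound presets emulate a circular denuded domain that refills
## with initially wispy, randomly aligned fibrils and re-aligns over the
## repair timecourse.  Stages are independent draws, not a time-evolution
## model.

.FIBRIL_DENSITY_SPARSE <- 120   # fibrils per 512^2 image, early wisps
.FIBRIL_DENSITY_DENSE <- 600    # fibrils per 512^2 image, mature lattice

.scaleCount <- function(base, size) max(1L, as.integer(round(base * (size / 512)^2)))

#' Developmental stage presets
#'
#' Returns the default three-stage developmental series: a sparse entirely
#' random stage (\code{kappa = 0}), a loosely orthogonal two-family stage
#' (\code{kappa = 3}) and a tight orthogonal lattice (\code{kappa = 20}).
#' The two families default to 45 and 135 degrees so that each falls inside
#' one range of the 0--90 / 90--180 split; their absolute orientation is a
#' free parameter.
#'
#' @param size image side in pixels; fibril counts scale with image area.
#' @param mu numeric length 2, orientations of the two lattice families.
#'
#' @return a list of stages, each a list with elements \code{label},
#'   \code{mixture} (an \linkS4class{OrientationMixture}) and \code{nFibrils}.
#'
#' @examples
#' str(developmentalStages(size = 256), max.level = 1)
#'
#' @export
developmentalStages <- function(size = 512, mu = c(45, 135)) {
  list(
    list(label = "2dpf", mixture = OrientationMixture(mu = mu[1], kappa = 0),
         nFibrils = .scaleCount(.FIBRIL_DENSITY_SPARSE, size)),
    list(label = "3dpf", mixture = OrientationMixture(mu = mu, kappa = 3),
         nFibrils = .scaleCount(.FIBRIL_DENSITY_DENSE, size)),
    list(label = "4dpf", mixture = OrientationMixture(mu = mu, kappa = 20),
         nFibrils = .scaleCount(.FIBRIL_DENSITY_DENSE, size)))
}

#' Generate a developmental image series with ground truth
#'
#' Renders one synthetic fibril image per developmental stage, returning the
#' ground-truth orientations alongside each image so that the Fourier
#' analysis can be validated against the direct Alignment Index of the true
#' angles.
#'
#' @param stages a stage list as returned by [developmentalStages()].
#' @param size image side in pixels.
#' @param seed integer seed; stage \code{i} uses a sub-seed derived
#'   deterministically from \code{seed} and \code{i}.
#' @param ... further scene parameters passed to [simulateFibrilScene()]
#'   (e.g. \code{segmentLength}, \code{noiseSigma}).
#'
#' @return a list with one element per stage, each a list of \code{label},
#'   \code{image} (numeric matrix), \code{truth}
#'   (\linkS4class{OrientationSample}) and \code{scene}
#'   (\linkS4class{FibrilScene}).
#'
#' @examples
#' dev <- makeDevelopmentalSeries(developmentalStages(size = 128),
#'                                size = 128, seed = 1)
#' ## AI of each stage's dominant fibril family (angles in [0, 90))
#' sapply(dev, function(s) {
#'   th <- angles(s$truth)
#'   alignmentIndex(th[th < 90])
#' })
#'
#' @export
makeDevelopmentalSeries <- function(stages = developmentalStages(size),
                                    size = 512, seed, ...) {
  if (!length(stages)) stop("at least one stage is required")
  lapply(seq_along(stages), function(i) {
    st <- stages[[i]]
    sim <- simulateFibrilScene(st$mixture, st$nFibrils, size = size,
                               seed = deriveSeed(seed, i), ...)
    list(label = st$label, image = renderScene(sim$scene),
         truth = sim$truth, scene = sim$scene)
  })
}

#' Wound-repair timepoint presets
#'
#' Default post-injury timecourse for [makeWoundSeries()]: the wound disk is
#' first devoid of fibrils, then refills at half density with entirely
#' random wispy fibrils, then approaches full density with increasingly
#' orthogonal alignment until it matches the unwounded lattice.  The final
#' preset's parameters equal the unwounded lattice, which
#' [makeWoundSeries()] renders as full resolution (no trace of a defect).
#'
#' @param mu numeric length 2, orientations of the orthogonal families.
#'
#' @return a list of timepoints, each a list with elements \code{label},
#'   \code{densityFraction} and \code{insideMixture}.
#'
#' @export
woundTimepoints <- function(mu = c(45, 135)) {
  list(
    list(label = "1dpi", densityFraction = 0,
         insideMixture = OrientationMixture(mu = mu[1], kappa = 0)),
    list(label = "5dpi", densityFraction = 0.5,
         insideMixture = OrientationMixture(mu = mu[1], kappa = 0)),
    list(label = "10dpi", densityFraction = 0.8,
         insideMixture = OrientationMixture(mu = mu, kappa = 5)),
    list(label = "16dpi", densityFraction = 1,
         insideMixture = OrientationMixture(mu = mu, kappa = 20)))
}

## Lattice segments for a wound scenario, flagging every segment whose body
## (not merely its centre) intersects the wound disk: the denuded domain is
## collagen-free with a clear edge, as in a fresh stab wound.
.woundLattice <- function(scenario, seed) {
  sim <- simulateFibrilScene(scenario@outsideMixture, scenario@nFibrils,
                             size = scenario@size,
                             segmentLength = scenario@segmentLength,
                             segmentThickness = scenario@segmentThickness,
                             amplitude = scenario@amplitude,
                             psfSigma = scenario@psfSigma,
                             background = scenario@background,
                             noiseSigma = 0, seed = seed)
  seg <- sim$scene@segments
  ## distance from the wound centre to each segment (clamped projection)
  dx <- cos(.deg2rad(seg$angle)); dy <- sin(.deg2rad(seg$angle))
  vx <- scenario@woundCenter[1] - seg$x
  vy <- scenario@woundCenter[2] - seg$y
  t <- pmin(seg$length / 2, pmax(-seg$length / 2, vx * dx + vy * dy))
  dist <- sqrt((vx - t * dx)^2 + (vy - t * dy)^2)
  inside <- dist <= scenario@woundRadius + seg$thickness / 2
  list(segments = seg, inside = inside, truth = sim$truth)
}

## Fibrils deposited inside the wound disk: centres uniform over the disk,
## count set by the density fraction times the outside areal density over
## the disk area; segments may poke beyond the wound edge (new collagen
## bonds onto the surrounding fibrils), which the outside-mask reach
## accounts for.
.woundInfill <- function(scenario, densityFraction, insideMixture, seed,
                         wispFactor = 0.5) {
  size <- scenario@size
  areal <- scenario@nFibrils / size^2
  ## regenerating collagen is wispy: finer, shorter filaments than the
  ## mature lattice; count is scaled up so the total deposited length per
  ## area matches densityFraction times the outside lattice
  wispLength <- wispFactor * scenario@segmentLength
  n <- as.integer(round(densityFraction * areal * pi *
                          scenario@woundRadius^2 / wispFactor))
  if (n < 1L)
    return(list(segments = data.frame(x = numeric(), y = numeric(),
                                      angle = numeric(), length = numeric(),
                                      thickness = numeric(),
                                      amplitude = numeric()),
                truth = OrientationSample()))
  ang <- angles(sampleOrientations(insideMixture, n, seed = deriveSeed(seed, 1L)))
  rmax <- scenario@woundRadius
  seg <- withSeed(deriveSeed(seed, 2L), {
    rr <- rmax * sqrt(stats::runif(n))
    aa <- stats::runif(n, 0, 2 * pi)
    data.frame(
      x = scenario@woundCenter[1] + rr * cos(aa),
      y = scenario@woundCenter[2] + rr * sin(aa),
      angle = ang,
      length = pmin(1.6 * wispLength,
                    pmax(6, stats::rnorm(n, wispLength, 0.2 * wispLength))),
      thickness = rep(0.8 * scenario@segmentThickness, n),
      amplitude = scenario@amplitude * stats::runif(n, 0.7, 1.3))
  })
  list(segments = seg, truth = OrientationSample(angles = ang))
}

.sameMixture <- function(a, b) {
  identical(a@mu, b@mu) && identical(a@kappa, b@kappa) &&
    identical(a@weight, b@weight)
}

#' Generate a wound-repair image series with ground truth
#'
#' Renders one composite image per timepoint.  The unwounded lattice
#' outside the wound disk is generated once from \code{seed} and is
#' identical across timepoints; fibrils inside the disk are drawn per
#' timepoint according to its density fraction and orientation mixture.
#' The Gaussian noise field is also drawn once, so pixels outside the
#' wound's influence are bit-identical across the series.
#'
#' @param scenario a \linkS4class{WoundScenario} providing the lattice and
#'   wound geometry (its own \code{densityFraction}/\code{insideMixture}
#'   are overridden by each timepoint).
#' @param timepoints a list as returned by [woundTimepoints()].
#' @param seed integer seed.
#'
#' @return a list with one element per timepoint, each a list of
#'   \code{label}, \code{image}, \code{insideTruth} and \code{outsideTruth}
#'   (\linkS4class{OrientationSample}s of the wound-domain and lattice
#'   orientations), and \code{masks}: logical matrices \code{inside} (the
#'   wound disk) and \code{outside} (pixels beyond the reach of any
#'   inside-wound fibril, where the series is pixel-identical).
#'
#' @examples
#' ws <- WoundScenario(size = 128, nFibrils = 40)
#' series <- makeWoundSeries(ws, woundTimepoints()[c(1, 4)], seed = 1)
#' sapply(series, `[[`, "label")
#'
#' @export
makeWoundSeries <- function(scenario, timepoints = woundTimepoints(), seed) {
  stopifnot(is(scenario, "WoundScenario"))
  validObject(scenario)
  if (!length(timepoints)) stop("at least one timepoint is required")
  size <- scenario@size
  lat <- .woundLattice(scenario, seed = deriveSeed(seed, 1000L))
  outSeg <- lat$segments[!lat$inside, , drop = FALSE]
  noise <- if (scenario@noiseSigma > 0)
    withSeed(deriveSeed(seed, 2000L),
             matrix(stats::rnorm(size^2, 0, scenario@noiseSigma), size, size))
  else matrix(0, size, size)
  ctr <- scenario@woundCenter
  D <- sqrt(outer(((1:size) - ctr[2])^2, ((1:size) - ctr[1])^2, `+`))
  ## reach of wound-dependent content: a restored lattice segment touching
  ## the disk edge can extend a full (clamped) segment length beyond it,
  ## plus thickness and the support of the blur kernel
  reach <- scenario@woundRadius + 1.6 * scenario@segmentLength +
    scenario@segmentThickness + .blurReach(scenario@psfSigma) + 2
  masks <- list(inside = D <= scenario@woundRadius, outside = D > reach)
  lapply(seq_along(timepoints), function(i) {
    tp <- timepoints[[i]]
    ## a timepoint whose parameters equal the unwounded lattice is fully
    ## resolved: no trace of a defect remains, so the undisturbed lattice
    ## itself is rendered (only pixels within the wound's reach change)
    resolved <- tp$densityFraction >= 1 &&
      .sameMixture(tp$insideMixture, scenario@outsideMixture)
    if (resolved) {
      segs <- lat$segments
      insideTruth <- OrientationSample(
        angles = lat$segments$angle[lat$inside])
    } else {
      infill <- .woundInfill(scenario, tp$densityFraction, tp$insideMixture,
                             seed = deriveSeed(seed, 3000L + i))
      segs <- rbind(outSeg, infill$segments)
      insideTruth <- infill$truth
    }
    scene <- FibrilScene(size = size, segments = segs,
                         psfSigma = scenario@psfSigma,
                         background = scenario@background,
                         noiseSigma = 0, seed = NA_real_)
    img <- pmax(renderScene(scene) + noise, 0)
    list(label = tp$label, image = img,
         insideTruth = insideTruth,
         outsideTruth = OrientationSample(angles = outSeg$angle),
         masks = masks, scene = scene)
  })
}

#' Crop the analysis window inscribed in a wound disk
#'
#' Returns the largest axis-aligned square fully inscribed in the wound
#' disk, the window on which wound-domain Alignment Index is computed
#' (masking is applied by cropping upstream of the Fourier stage).
#'
#' @param image numeric matrix.
#' @param center numeric length 2, wound centre (x, y) in pixels.
#' @param radius wound radius in pixels.
#'
#' @return a square numeric matrix of side \code{2 * floor(radius / sqrt(2))}.
#'
#' @export
cropWound <- function(image, center, radius) {
  stopifnot(is.matrix(image), radius > 0)
  h <- floor(radius / sqrt(2))
  if (h < 4) stop("wound radius too small to crop an analysis window")
  rows <- (round(center[2]) - h + 1):(round(center[2]) + h)
  cols <- (round(center[1]) - h + 1):(round(center[1]) + h)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(image) ||
      max(cols) > ncol(image))
    stop("wound analysis window exceeds image bounds")
  image[rows, cols]
}
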