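#' Mean orientation angle of axial data
#'
#' Computes the mean orientation angle \eqn{\theta_{th}} of a set of axial
#' angular measurements (orientations defined modulo 180 degrees), using the
#' doubled-angle circular mean
#' \eqn{\theta_{th} = \tfrac{1}{2}\,\mathrm{atan2}(\sum w \sin 2\theta,
#' \sum w \cos 2\theta)} mapped into [0, 180).
#'
#' For a histogram the bin centres are used as the measurements and the bin
#' values as weights.  If the total weight is zero the signal is degenerate
#' and \code{NA} is returned with attribute \code{degenerate = TRUE}.  If the
#' doubled-angle resultant length is numerically zero (e.g. exactly balanced
#' perpendicular masses) the orientation is ambiguous; the smaller-angle
#' solution in [0, 90) is returned with attribute \code{ambiguous = TRUE}.
#'
#' @param x an \linkS4class{OrientationSample}, an
#'   \linkS4class{OrientationHistogram}, or a numeric vector of angles in
#'   degrees in [0, 180).
#' @param ... passed to methods; the numeric method accepts \code{weights}.
#'
#' @return a length-one numeric, degrees in [0, 180); possibly \code{NA}.
#'
#' @examples
#' circularMeanOrientation(c(10, 30))   # 20
#' circularMeanOrientation(c(170, 10))  # 0 (axial wrap-around)
#'
#' @seealso [alignmentIndex()]
#' @export
setGeneric("circularMeanOrientation", function(x, ...)
  standardGeneric("circularMeanOrientation"))

#' Alignment Index (AI) of axial orientation data
#'
#' The Alignment Index is the doubled-angle (2D nematic) order parameter
#' \deqn{AI = \left|\frac{1}{N}\sum_{i=1}^N \left(2\cos^2(\theta_i -
#' \theta_{th}) - 1\right)\right| =
#' \left|\frac{\sum_i w_i \cos 2(\theta_i - \theta_{th})}{\sum_i w_i}\right|}
#' where \eqn{\theta_i} are angular measurements (or histogram bin centres
#' weighted by bin values) and \eqn{\theta_{th}} is the mean orientation
#' angle.  AI = 1 reflects zero angular dispersion (full alignment) and
#' AI = 0 an entirely random (uniform over [0, 180)) orientation
#' distribution.
#'
#' @param x an \linkS4class{OrientationSample}, an
#'   \linkS4class{OrientationHistogram}, or a numeric vector of angles in
#'   degrees in [0, 180).
#' @param theta the reference mean orientation \eqn{\theta_{th}} in degrees;
#'   when \code{NULL} (default) it is computed from \code{x} with
#'   [circularMeanOrientation()].
#' @param ... passed to methods; the numeric method accepts \code{weights}.
#'
#' @return a length-one numeric in [0, 1].  Zero total weight yields 0 with
#'   attribute \code{degenerate = TRUE}.
#'
#' @examples
#' alignmentIndex(rep(37, 100))          # exactly 1
#' alignmentIndex(0:179)                 # 0 up to rounding
#' alignmentIndex(c(10, 30), theta = 20) # cos(20 deg)
#'
#' @export
setGeneric("alignmentIndex", function(x, theta = NULL, ...)
  standardGeneric("alignmentIndex"))

#' @rdname OrientationSample-class
#' @param x an object.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname OrientationHistogram-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname OrientationHistogram-class
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname OrientationHistogram-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname OrientationHistogram-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname OrientationHistogram-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname AIResult-class
#' @export
setGeneric("aiLow", function(x) standardGeneric("aiLow"))

#' @rdname AIResult-class
#' @export
setGeneric("aiHigh", function(x) standardGeneric("aiHigh"))

#' @rdname AIResult-class
#' @export
setGeneric("aiCombined", function(x) standardGeneric("aiCombined"))

#' @rdname AIResult-class
#' @export
setGeneric("aiDominant", function(x) standardGeneric("aiDominant"))

#' @rdname AIResult-class
#' @export
setGeneric("thetaLow", function(x) standardGeneric("thetaLow"))

#' @rdname AIResult-class
#' @export
setGeneric("thetaHigh", function(x) standardGeneric("thetaHigh"))

#' @rdname AIResult-class
#' @export
setGeneric("rangeMasses", function(x) standardGeneric("rangeMasses"))
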