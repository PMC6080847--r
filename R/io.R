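## TIFF image I/O and ground-truth export.

#' Read a single-channel TIFF image
#'
#' Reads an 8/16-bit integer or 32-bit float single-channel TIFF into a
#' numeric matrix (integer images are returned on the [0, 1] scale used by
#' the `tiff` package).  Multi-channel input is rejected with an error
#' asking for channel selection, and multi-directory (stack) TIFFs are
#' rejected: the analysis operates on single-channel maximum-intensity
#' projections.
#'
#' @param path path to a TIFF file.
#' @return a numeric matrix.
#' @seealso [writeImageTiff()]
#' @export
readImageTiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) != 1L)
    stop("multi-image TIFF stacks are not supported; project first: ", path)
  img <- img[[1L]]
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop("multi-channel TIFF; select a single channel before analysis: ",
              path)
  }
  if (length(dim(img)) != 2L) stop("not a 2D image: ", path)
  storage.mode(img) <- "double"
  img
}

#' Write an intensity image as a single-channel 32-bit float TIFF
#'
#' TIFF storage holds values on the [0, 1] scale, so an image whose maximum
#' exceeds 1 is divided by its maximum before writing.  The orientation
#' analysis is invariant to a global intensity scale (the spectrum is
#' mean-subtracted and the Alignment Index is a weighted mean of cosines),
#' so rescaling does not affect any downstream result.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param path output path.
#' @return the scale factor that was divided out (1 if none), invisibly.
#' @export
writeImageTiff <- function(image, path) {
  stopifnot(is.matrix(image), all(is.finite(image)), all(image >= 0))
  scale <- max(image, 1)
  tiff::writeTIFF(image / scale, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' Write the ground truth of a synthetic scene
#'
#' Writes the segment table (x, y, angle_deg, length, thickness, amplitude)
#' as CSV and the scene parameters as JSON next to it.
#'
#' @param scene a \linkS4class{FibrilScene}.
#' @param csvPath path for the segment table CSV.
#' @param jsonPath path for the scene-parameter JSON; default replaces the
#'   CSV extension.
#' @return `csvPath`, invisibly.
#' @export
writeGroundTruth <- function(scene, csvPath,
                             jsonPath = sub("\\.csv$", ".json", csvPath)) {
  stopifnot(is(scene, "FibrilScene"))
  seg <- scene@segments
  names(seg)[names(seg) == "angle"] <- "angle_deg"
  utils::write.csv(seg, csvPath, row.names = FALSE)
  pars <- list(size = scene@size, psf_sigma = scene@psfSigma,
               background = scene@background, noise_sigma = scene@noiseSigma,
               poisson = scene@poisson, seed = scene@seed,
               n_segments = nrow(seg))
  jsonlite::write_json(pars, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
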