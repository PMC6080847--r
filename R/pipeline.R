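## Batch orchestration: simulate or ingest image sets, run the Fourier /
## Alignment Index analysis per image, assemble the group table, run the
## group statistics and write the result bundle.

#' Batch run configuration
#'
#' @slot mode \code{"simulate"} (generate images and a manifest),
#'   \code{"analyze"} (analyse images listed in a manifest CSV) or
#'   \code{"full"} (simulate, analyse and test in one run).
#' @slot preset simulation preset, \code{"developmental"} or
#'   \code{"wound"}.
#' @slot manifest path to a manifest CSV with columns \code{path},
#'   \code{group}, \code{timepoint}, \code{condition} (analyze mode);
#'   unknown columns are preserved in the group table.
#' @slot outdir output directory.
#' @slot seed integer seed; every stochastic step derives its sub-seed from
#'   it.
#' @slot nPerGroup images simulated per group.
#' @slot imageSize synthetic image side in pixels.
#' @slot params a \linkS4class{DirectionalityParams}.
#' @slot backgroundMethod background-subtraction rule for
#'   [subtractBackground()].
#' @slot varEqual logical, pooled-variance t tests instead of Welch.
#' @slot writeImages logical, write simulated images as TIFF in full mode
#'   (simulate mode always writes them).
#'
#' @param ... slot values replacing the defaults (see slots above).
#' @return \code{RunConfig()} returns a RunConfig object.
#'
#' @aliases RunConfig
#' @export RunConfig
#' @exportClass RunConfig
RunConfig <- setClass("RunConfig",
  slots = c(mode = "character", preset = "character", manifest = "character",
            outdir = "character", seed = "numeric", nPerGroup = "integer",
            imageSize = "integer", params = "DirectionalityParams",
            backgroundMethod = "character", varEqual = "logical",
            writeImages = "logical"),
  prototype = list(mode = "full", preset = "developmental",
                   manifest = NA_character_, outdir = ".", seed = 1,
                   nPerGroup = 10L, imageSize = 256L,
                   backgroundMethod = "min", varEqual = FALSE,
                   writeImages = FALSE),
  validity = function(object) {
    if (!object@mode %in% c("simulate", "analyze", "full"))
      return("mode must be simulate, analyze or full")
    if (!object@preset %in% c("developmental", "wound"))
      return("preset must be developmental or wound")
    if (object@mode == "analyze" && is.na(object@manifest))
      return("analyze mode requires a manifest path")
    if (object@nPerGroup < 1L) return("nPerGroup must be >= 1")
    if (object@imageSize < 32L) return("imageSize must be >= 32")
    TRUE
  })

setMethod("initialize", "RunConfig",
  function(.Object, nPerGroup = 10L, imageSize = 256L,
           params = DirectionalityParams(), ...) {
    callNextMethod(.Object, nPerGroup = as.integer(nPerGroup),
                   imageSize = as.integer(imageSize), params = params, ...)
  })

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: mode %s, preset %s, n/group %d, image %d px, seed %g\n",
    object@mode, object@preset, object@nPerGroup, object@imageSize,
    object@seed))
})

.configHash <- function(config) {
  txt <- paste(deparse(list(
    mode = config@mode, preset = config@preset, manifest = config@manifest,
    seed = config@seed, nPerGroup = config@nPerGroup,
    imageSize = config@imageSize, bins = config@params@bins,
    window = config@params@window, fmin = config@params@fmin,
    fmax = config@params@fmax, padPow2 = config@params@padPow2,
    backgroundMethod = config@backgroundMethod,
    varEqual = config@varEqual)), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

## One simulated record per image: id/group/timepoint/condition + the image
## to analyse (wound images are cropped to the wound analysis window).
.simulateRecords <- function(config) {
  size <- config@imageSize
  seed <- config@seed
  if (config@preset == "developmental") {
    stages <- developmentalStages(size)
    recs <- list()
    for (s in seq_along(stages)) {
      st <- stages[[s]]
      for (i in seq_len(config@nPerGroup)) {
        sim <- simulateFibrilScene(st$mixture, st$nFibrils, size = size,
                                   seed = deriveSeed(seed, s * 100000 + i))
        recs[[length(recs) + 1L]] <- list(
          image_id = sprintf("%s_%02d", st$label, i), group = st$label,
          timepoint = st$label, condition = "unwounded",
          image = renderScene(sim$scene), scene = sim$scene,
          truth = sim$truth)
      }
    }
    return(recs)
  }
  ## wound preset: per timepoint, wounded fish (wound crop analysed) and
  ## unwounded sibling fish (same lattice statistics, same window)
  tps <- woundTimepoints()
  n <- .scaleCount(.FIBRIL_DENSITY_DENSE, size)
  recs <- list()
  for (t in seq_along(tps)) {
    tp <- tps[[t]]
    for (i in seq_len(config@nPerGroup)) {
      sc <- WoundScenario(size = size, nFibrils = n,
                          densityFraction = tp$densityFraction,
                          insideMixture = tp$insideMixture, label = tp$label)
      wr <- makeWoundSeries(sc, list(tp),
                            seed = deriveSeed(seed, t * 1000000 + i))[[1L]]
      recs[[length(recs) + 1L]] <- list(
        image_id = sprintf("%s_wounded_%02d", tp$label, i),
        group = paste0(tp$label, "_wounded"), timepoint = tp$label,
        condition = "wounded",
        image = cropWound(wr$image, sc@woundCenter, sc@woundRadius),
        fullImage = wr$image, scene = wr$scene, truth = wr$insideTruth)
      sim <- simulateFibrilScene(sc@outsideMixture, n, size = size,
                                 seed = deriveSeed(seed,
                                                   t * 1000000 + 500000 + i))
      recs[[length(recs) + 1L]] <- list(
        image_id = sprintf("%s_unwounded_%02d", tp$label, i),
        group = paste0(tp$label, "_unwounded"), timepoint = tp$label,
        condition = "unwounded",
        image = cropWound(renderScene(sim$scene), sc@woundCenter,
                          sc@woundRadius),
        scene = sim$scene, truth = sim$truth)
    }
  }
  recs
}

.analyzeRecords <- function(recs, config) {
  rows <- lapply(recs, function(r) {
    row <- data.frame(image_id = r$image_id, group = r$group,
                      timepoint = r$timepoint, condition = r$condition,
                      status = "ok")
    res <- tryCatch(
      analyzeImage(r$image, config@params,
                   backgroundMethod = config@backgroundMethod),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- paste("failed:", conditionMessage(res))
      ai <- as.data.frame(new("AIResult", aiLow = 0, aiHigh = 0,
                              thetaLow = NA_real_, thetaHigh = NA_real_,
                              massLow = 0, massHigh = 0, aiCombined = 0,
                              degenerateLow = TRUE, degenerateHigh = TRUE))
      ai[] <- NA
      return(cbind(row, ai))
    }
    if (res@degenerateLow || res@degenerateHigh)
      message("degenerate AI range(s) for image ", r$image_id)
    cbind(row, as.data.frame(res))
  })
  do.call(rbind, rows)
}

.groupStats <- function(groupTable, config) {
  ok <- groupTable[!is.na(groupTable$ai), , drop = FALSE]
  conds <- unique(as.character(ok$condition))
  if (all(c("wounded", "unwounded") %in% conds))
    return(woundedVsUnwoundedTTests(ok, var.equal = config@varEqual))
  if (length(unique(as.character(ok$group))) >= 2L)
    return(anovaTukey(ok))
  stop("nothing to test: fewer than two groups")
}

#' Run a batch simulation / analysis
#'
#' Executes the configured batch: \code{simulate} writes synthetic images
#' (TIFF), their ground truth (CSV/JSON) and a manifest CSV;
#' \code{analyze} reads a manifest of images and produces per-image
#' Alignment Index rows, the group table and the group statistics;
#' \code{full} does both in one pass (images kept in memory unless
#' \code{writeImages}).  All outputs are deterministic given the seed, and
#' the run manifest (JSON) records the configuration and its hash so a run
#' can be reproduced bit for bit.  Unreadable images in analyze mode are
#' recorded as failed rows and the run continues.
#'
#' @param config a \linkS4class{RunConfig}.
#'
#' @return invisibly, a list with (depending on mode) \code{aiTable},
#'   \code{groupTable}, \code{report}, \code{summary}, \code{manifest} and
#'   \code{files} (paths written).
#'
#' @examples
#' \donttest{
#' cfg <- RunConfig(mode = "full", preset = "developmental",
#'                  nPerGroup = 3, imageSize = 96, seed = 1,
#'                  outdir = tempfile("run"))
#' res <- runBatch(cfg)
#' res$summary
#' }
#'
#' @export
runBatch <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  outdir <- config@outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  writeOut <- function(obj, name) {
    p <- file.path(outdir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    files[[name]] <<- p
    p
  }
  manifestJson <- function(extra = list()) {
    p <- file.path(outdir, "run_manifest.json")
    jsonlite::write_json(c(list(
      mode = config@mode, preset = config@preset, seed = config@seed,
      n_per_group = config@nPerGroup, image_size = config@imageSize,
      bins = config@params@bins, window = config@params@window,
      fmin = config@params@fmin, fmax = config@params@fmax,
      background_method = config@backgroundMethod,
      var_equal = config@varEqual,
      config_hash = .configHash(config)), extra),
      p, auto_unbox = TRUE, digits = NA)
    files[["run_manifest.json"]] <<- p
    p
  }

  if (config@mode == "analyze") {
    man <- utils::read.csv(config@manifest, stringsAsFactors = FALSE)
    need <- c("path", "group", "timepoint", "condition")
    miss <- setdiff(need, names(man))
    if (length(miss))
      stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
    if (!nrow(man)) stop("empty manifest")
    recs <- lapply(seq_len(nrow(man)), function(i) {
      p <- man$path[i]
      if (!file.exists(p))
        p <- file.path(dirname(config@manifest), man$path[i])
      img <- tryCatch(readImageTiff(p), error = function(e) e)
      list(image_id = basename(man$path[i]), group = man$group[i],
           timepoint = man$timepoint[i], condition = man$condition[i],
           image = if (inherits(img, "error")) NULL else img,
           readError = if (inherits(img, "error"))
             conditionMessage(img) else NULL)
    })
    ## surface read failures as failed rows, keep going
    recs <- lapply(recs, function(r) {
      if (is.null(r$image)) r$image <- "unreadable"
      r
    })
  } else {
    t0 <- proc.time()[["elapsed"]]
    recs <- .simulateRecords(config)
    message(sprintf("simulated %d images in %.1f s", length(recs),
                    proc.time()[["elapsed"]] - t0))
  }

  if (config@mode %in% c("simulate", "full") &&
      (config@mode == "simulate" || config@writeImages)) {
    imgdir <- file.path(outdir, "images")
    dir.create(imgdir, recursive = TRUE, showWarnings = FALSE)
    manRows <- lapply(recs, function(r) {
      img <- if (!is.null(r$fullImage)) r$fullImage else r$image
      tif <- file.path(imgdir, paste0(r$image_id, ".tif"))
      writeImageTiff(img, tif)
      writeGroundTruth(r$scene,
                       file.path(imgdir, paste0(r$image_id, "_truth.csv")))
      data.frame(path = file.path("images", paste0(r$image_id, ".tif")),
                 group = r$group, timepoint = r$timepoint,
                 condition = r$condition)
    })
    writeOut(do.call(rbind, manRows), "manifest.csv")
  }

  result <- list(files = files)
  if (config@mode == "simulate") {
    manifestJson(list(n_images = length(recs)))
    result$files <- files
    result$manifest <- file.path(outdir, "manifest.csv")
    return(invisible(result))
  }

  aiTable <- .analyzeRecords(recs, config)
  groupTable <- aiTable[, c("image_id", "group", "timepoint", "condition")]
  groupTable$ai <- aiTable$ai_combined
  groupTable$status <- aiTable$status
  writeOut(aiTable, "ai_results.csv")
  writeOut(groupTable, "group_table.csv")
  summaryTable <- summarizeGroups(groupTable[!is.na(groupTable$ai), ])
  writeOut(summaryTable, "group_summary.csv")
  report <- .groupStats(groupTable, config)
  writeOut(report, "test_report.csv")
  jsonlite::write_json(report, file.path(outdir, "test_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files[["test_report.json"]] <- file.path(outdir, "test_report.json")
  manifestJson(list(n_images = length(recs)))
  invisible(list(aiTable = aiTable, groupTable = groupTable,
                 summary = summaryTable, report = report, files = files))
}

#' Emulate the developmental and wound-repair timecourse analyses
#'
#' Runs the two standard synthetic timecourses end to end and returns both
#' labelled result bundles: \code{development} (three developmental stages,
#' one-way ANOVA with Tukey comparisons; group mean AI rises across
#' stages) and \code{wound} (wounded versus unwounded at each post-injury
#' timepoint, t tests; the wounded mean rises toward the unwounded mean
#' until the late comparison is non-significant).
#'
#' @param seed integer seed.
#' @param outdir optional output directory; when given, each bundle is
#'   written to a subdirectory via [runBatch()].
#' @param nPerGroup images per group (default 12).
#' @param imageSize synthetic image side in pixels.
#'
#' @return a list with elements \code{development} and \code{wound}, each a
#'   result bundle as returned by [runBatch()].
#'
#' @examples
#' \donttest{
#' res <- emulateFigureTimecourses(seed = 1, nPerGroup = 3, imageSize = 96)
#' res$development$summary
#' res$wound$report
#' }
#'
#' @export
emulateFigureTimecourses <- function(seed, outdir = NULL, nPerGroup = 12,
                                     imageSize = 256) {
  mk <- function(preset, sub, seedOffset) {
    od <- if (is.null(outdir)) tempfile(sub) else file.path(outdir, sub)
    cfg <- RunConfig(mode = "full", preset = preset, outdir = od,
                     seed = deriveSeed(seed, seedOffset),
                     nPerGroup = nPerGroup, imageSize = imageSize,
                     writeImages = FALSE)
    runBatch(cfg)
  }
  list(development = mk("developmental", "development", 1L),
       wound = mk("wound", "wound-repair", 2L))
}
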