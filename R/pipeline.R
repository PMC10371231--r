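#' @include AllGenerics.R preprocess.R romt.R glad.R voxel-stats.R io.R
NULL

#' Configure an end-to-end two-cohort study
#'
#' Bundles the per-module configurations for a full simulate -> preprocess
#' -> rOMT -> pathline -> statistics run on two synthetic cohorts. Each
#' subject gets a deterministic seed derived from the global seed, so a
#' rerun with an identical configuration reproduces every numeric output
#' bitwise.
#'
#' @param specA,specB template \code{\link{phantomSpec}}s for the two
#'   cohorts (their \code{seed} fields are overridden per subject).
#' @param nPerGroup subjects per cohort (>= 2).
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param romt a \code{\link{romtConfig}}.
#' @param seedThreshold,retainVox pathline seeding and retention settings.
#' @param fwhm,alpha group-statistics smoothing (mm) and significance
#'   level.
#' @param region optional logical array marking a subregion of interest
#'   (e.g. the planted velocity-contrast sphere) for the regional report.
#' @param paths optional named character vector of required input files
#'   (e.g. external masks); checked for existence before any compute.
#' @param seed global integer seed.
#' @return list of class \code{"StudyConfig"}.
#' @export
studyConfig <- function(specA, specB, nPerGroup = 5L,
                        preprocess = preprocessConfig(),
                        romt = romtConfig(),
                        seedThreshold = 0.1, retainVox = 0.5,
                        fwhm = 0.4, alpha = 0.05, region = NULL,
                        paths = NULL, seed = 1L) {
  stopifnot(inherits(specA, "PhantomSpec"), inherits(specB, "PhantomSpec"))
  if (nPerGroup < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  structure(list(specA = specA, specB = specB,
                 nPerGroup = as.integer(nPerGroup), preprocess = preprocess,
                 romt = romt, seedThreshold = seedThreshold,
                 retainVox = retainVox, fwhm = fwhm, alpha = alpha,
                 region = region, paths = paths, seed = as.integer(seed)),
            class = "StudyConfig")
}

#' Run one subject through the transport pipeline
#'
#' simulate -> preprocess -> rOMT solve -> pathline tracing -> speed map.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param romt a \code{\link{romtConfig}}.
#' @param seedThreshold,retainVox pathline settings.
#' @return list: speedMap, metrics (whole-domain transport metrics),
#'   solutions, truth.
#' @export
runSubject <- function(spec, preprocess = preprocessConfig(),
                       romt = romtConfig(), seedThreshold = 0.1,
                       retainVox = 0.5) {
  truth <- makeVelocityField(spec)
  series <- simulateTracerSeries(spec, truth)
  pc <- preprocessSeries(series, preprocess)
  sols <- solveSeries(pc, romt)
  paths <- tracePathlines(sols, seedThreshold = seedThreshold,
                          retainVox = retainVox)
  sm <- speedMap(paths)
  mask <- gridMask(pc@grid, "brain")
  list(speedMap = sm, metrics = transportMetrics(sm, mask),
       solutions = sols, truth = truth)
}

#' Execute a full two-cohort group study
#'
#' Runs every subject of both cohorts through
#' \code{\link{runSubject}}, assembles per-subject transport metrics,
#' computes the voxel-wise two-sample t map, and (when a region is
#' configured) reports the fraction of region voxels significant in each
#' direction plus the regional mean-speed ratio between cohorts. Any stage
#' failure aborts with the stage name and subject id.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param verbose print progress.
#' @return list of class \code{"StudyReport"}: \code{metrics} (data.frame),
#'   \code{statMap} (\linkS4class{StatMap}), \code{regionReport} (or NULL),
#'   \code{speedMaps}, \code{provenance}.
#' @export
runGroupStudy <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "StudyConfig"))
  if (!is.null(config$paths)) {
    missing <- config$paths[!file.exists(config$paths)]
    if (length(missing))
      stop("configuration error: missing input path(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  subjects <- list()
  metrics <- list()
  for (grp in c("A", "B")) {
    tmpl <- if (grp == "A") config$specA else config$specB
    off <- if (grp == "A") 0L else config$nPerGroup
    for (s in seq_len(config$nPerGroup)) {
      id <- sprintf("%s%02d", grp, s)
      spec <- tmpl
      spec$seed <- config$seed + 7919L * (off + s)
      res <- tryCatch(
        runSubject(spec, config$preprocess, config$romt,
                   config$seedThreshold, config$retainVox),
        error = function(e) stop("stage failure [subject ", id, "]: ",
                                 conditionMessage(e), call. = FALSE))
      subjects[[id]] <- res
      m <- res$metrics
      m$subject <- id
      m$group <- grp
      m$expectedMeanSpeed_um_s <- res$truth@expectedMeanSpeed
      metrics[[id]] <- m
      if (verbose)
        message(sprintf("subject %s: mean speed %.3g um/s (truth %.3g)",
                        id, m$meanSpeed_um_s, res$truth@expectedMeanSpeed))
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  idA <- grep("^A", names(subjects)); idB <- grep("^B", names(subjects))
  mapsA <- lapply(subjects[idA], function(x) x$speedMap)
  mapsB <- lapply(subjects[idB], function(x) x$speedMap)
  study <- groupStudy(mapsA, mapsB, fwhm = config$fwhm, alpha = config$alpha)
  stat <- ttestMap(study)

  regionReport <- NULL
  if (!is.null(config$region)) {
    reg <- as.logical(config$region) & as.logical(stat@included)
    regMean <- function(maps) {
      per <- vapply(maps, function(m) {
        v <- m@map[config$region & m@map > 0]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      mean(per, na.rm = TRUE)
    }
    mA <- regMean(mapsA); mB <- regMean(mapsB)
    regionReport <- list(
      nRegionVoxels = sum(config$region),
      nTested = sum(reg),
      fracSigBgtA = if (sum(reg)) sum(stat@sigBgtA[reg]) / sum(reg) else NA,
      fracSigAgtB = if (sum(reg)) sum(stat@sigAgtB[reg]) / sum(reg) else NA,
      regionalMeanSpeedA = mA, regionalMeanSpeedB = mB,
      regionalSpeedRatio = mB / mA)
  }
  structure(list(metrics = metrics, statMap = stat,
                 regionReport = regionReport,
                 speedMaps = list(A = mapsA, B = mapsB),
                 provenance = list(
                   package = as.character(utils::packageVersion("glymphflow")),
                   seed = config$seed,
                   romt = unclass(config$romt),
                   preprocess = unclass(config$preprocess),
                   seedThreshold = config$seedThreshold,
                   retainVox = config$retainVox,
                   fwhm = config$fwhm, alpha = config$alpha,
                   nPerGroup = config$nPerGroup)),
            class = "StudyReport")
}

#' Write the study report's numeric outputs
#'
#' Emits the per-subject metrics CSV and a JSON provenance record
#' sufficient to re-execute the study exactly.
#'
#' @param report a \code{"StudyReport"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(inherits(report, "StudyReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "subject_metrics.csv")
  write.csv(report$metrics, mpath, row.names = FALSE)
  ppath <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, ppath, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(metrics = mpath, provenance = ppath))
}
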