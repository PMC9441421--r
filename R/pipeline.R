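#' Default pipeline configuration
#'
#' Single source of truth for the pipeline (and command-line) defaults; each
#' value equals the corresponding stage function's documented default.
#'
#' @param outDir output directory.
#' @param seed master integer seed. Stage seeds derive from it by fixed
#'   offsets: the phantom uses \code{seed}, the cohort generator
#'   \code{seed + 1000}.
#' @return A named list (fields: \code{outDir}, \code{seed}, \code{stages},
#'   \code{preset}, \code{sigma}, \code{roiFile}, \code{slice},
#'   \code{adcRef}, \code{minAgeSubgroup}, \code{cohortFile},
#'   \code{observers}, \code{verbose}).
#' @export
defaultRunConfig <- function(outDir = "dwialps_out", seed = 1L) {
  list(
    outDir = outDir,
    seed = as.integer(seed),
    stages = c("simulate", "adc", "composite", "measure", "cohort"),
    preset = "default",
    sigma = 50,            # SNR 20 against the phantom's s0 = 1000
    roiFile = NULL,        # NULL: defaultRoiSet()
    slice = NULL,          # NULL: the ROI slice
    adcRef = 2.0,
    minAgeSubgroup = 40,
    cohortFile = NULL,     # NULL: simulate with defaultCohortSpec()
    observers = c("A", "B"),
    verbose = TRUE
  )
}

#' Compute the full set of cohort statistics
#'
#' Convenience wrapper running the four cohort analyses in one call:
#' inter-observer correlation, all-ages linear fit, strict over-\code{minAge}
#' subgroup linear fit, quadratic fit, and the decade-wise ANOVA with Tukey
#' post-hoc comparisons. The subgroup fit is \code{NULL} (with a message)
#' when fewer than 3 subjects pass the age filter.
#'
#' @param table cohort table.
#' @param minAge strict age cutoff for the subgroup fit (default 40).
#' @return list with elements \code{interobserver}, \code{linear},
#'   \code{subgroup}, \code{quadratic}, \code{anova}.
#' @export
cohortStatistics <- function(table, minAge = 40) {
  sub <- tryCatch(linearFit(table, minAge = minAge), error = function(e) {
    message("subgroup fit skipped: ", conditionMessage(e))
    NULL
  })
  list(
    interobserver = interobserverCorrelation(table),
    linear = linearFit(table),
    subgroup = sub,
    quadratic = quadraticFit(table),
    anova = decadeAnova(table)
  )
}

## internal: plain-list view of the statistics for JSON serialization
statsAsList <- function(stats) {
  reg <- function(f) {
    if (is.null(f)) return(NULL)
    list(model = f@model, coefficients = as.list(f@coefficients),
         r = f@r, R = f@R, vertex_age = f@vertexAge, n = f@n)
  }
  list(
    interobserver = list(r = stats$interobserver$r,
                         ci = stats$interobserver$ci,
                         icc21 = stats$interobserver$icc21,
                         n = stats$interobserver$n),
    linear = reg(stats$linear),
    subgroup_over_40 = reg(stats$subgroup),
    quadratic = reg(stats$quadratic),
    anova = list(F = stats$anova@fStatistic, p = stats$anova@pValue,
                 groups = stats$anova@groups, pairwise = stats$anova@pairwise)
  )
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the requested stages in order — simulate a phantom study,
#' compute ADC maps, render the directional composite, measure the ROIs for
#' each observer, and run the cohort statistics on a simulated cohort —
#' writing every artifact under \code{config$outDir} and a JSON manifest
#' recording files, parameters, seed and package version. With a fixed
#' config and seed the measurement CSV and statistics JSON are byte
#' reproducible.
#'
#' @param config configuration list, see [defaultRunConfig()].
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- utils::modifyList(defaultRunConfig(), config)
  log <- function(...) if (isTRUE(cfg$verbose)) message("[dwialps] ", sprintf(...))
  if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
  rel <- function(f) sub(paste0("^", cfg$outDir, "/?"), "", f)
  files <- character()
  study <- NULL; maps <- NULL

  if ("simulate" %in% cfg$stages) {
    log("simulate: phantom preset '%s', sigma %g, seed %d",
        cfg$preset, cfg$sigma, cfg$seed)
    spec <- defaultPhantomSpec(preset = cfg$preset, sigma = cfg$sigma)
    ph <- withStage("simulate", generatePhantom(spec, seed = cfg$seed))
    study <- ph$study
    f <- withStage("simulate", writeDiffusionStudy(study, cfg$outDir))
    truthFile <- file.path(cfg$outDir, "ground_truth.json")
    jsonlite::write_json(ph$truth, truthFile, auto_unbox = TRUE, digits = NA)
    files <- c(files, f, truthFile)
  }

  if ("adc" %in% cfg$stages) {
    if (is.null(study))
      study <- withStage("adc", readDiffusionStudy(cfg$outDir, "phantom"))
    log("adc: b = %g s/mm^2", bValue(study))
    maps <- withStage("adc", computeADC(study))
    files <- c(files, withStage("adc",
      writeADCMaps(maps, cfg$outDir, voxelSize = voxelSize(study))))
  }

  rois <- if (is.null(cfg$roiFile)) defaultRoiSet() else
    withStage("measure", readRoiSet(cfg$roiFile))

  if ("composite" %in% cfg$stages) {
    if (is.null(maps)) maps <- withStage("composite", readADCMaps(cfg$outDir))
    slice <- if (is.null(cfg$slice)) sliceIndex(rois) else cfg$slice
    log("composite: slice %d, adcRef %g", slice, cfg$adcRef)
    img <- withStage("composite", renderComposite(maps, slice, cfg$adcRef))
    f <- file.path(cfg$outDir, "composite.png")
    withStage("composite", writeComposite(img, f))
    files <- c(files, f)
  }

  if ("measure" %in% cfg$stages) {
    if (is.null(study))
      study <- withStage("measure", readDiffusionStudy(cfg$outDir, "phantom"))
    log("measure: slice %d, observers %s", sliceIndex(rois),
        paste(cfg$observers, collapse = ","))
    ms <- lapply(cfg$observers, function(ob)
      withStage("measure", measureSubject(study, rois, observerID = ob)))
    f <- file.path(cfg$outDir, "measurements.csv")
    writeMeasurements(ms, f)
    files <- c(files, f)
  }

  if ("cohort" %in% cfg$stages) {
    tab <- if (is.null(cfg$cohortFile)) {
      log("cohort: simulating default cohort, seed %d", cfg$seed + 1000L)
      generateCohort(defaultCohortSpec(), seed = cfg$seed + 1000L)
    } else {
      withStage("cohort", readCohortTable(cfg$cohortFile))
    }
    cohortFile <- file.path(cfg$outDir, "cohort.csv")
    writeCohortTable(tab, cohortFile)
    stats <- withStage("cohort", cohortStatistics(tab, minAge = cfg$minAgeSubgroup))
    statsFile <- file.path(cfg$outDir, "stats.json")
    jsonlite::write_json(statsAsList(stats), statsFile,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    plotCohort(tab, stats$linear, stats$subgroup, stats$quadratic,
               stats$anova, outDir = cfg$outDir)
    files <- c(files, cohortFile, statsFile,
               file.path(cfg$outDir, c("age_trajectory.png", "decade_boxplot.png")))
  }

  manifest <- list(
    package = "dwialps",
    version = as.character(utils::packageVersion("dwialps")),
    seed = cfg$seed,
    parameters = cfg[c("preset", "sigma", "adcRef", "minAgeSubgroup",
                       "observers", "stages")],
    files = unname(rel(files))
  )
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("done: %d artifacts in %s", length(files), cfg$outDir)
  invisible(manifest)
}
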