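#' Measure per-ROI per-axis mean diffusivities
#'
#' Averages each axis ADC over the valid voxels of each circular region on
#' the ROI slice. Voxel membership is by center distance:
#' (row - c_row)^2 + (col - c_col)^2 <= radius^2, boundary inclusive, so
#' voxel counts are bit-reproducible.
#'
#' @param maps an \linkS4class{ADCMaps}.
#' @param rois a \linkS4class{RoiSet}; every region voxel must be in bounds
#'   and every region must contain at least one valid voxel.
#' @return data.frame with one row per region: \code{label},
#'   \code{n_voxels}, \code{n_valid}, \code{mean_x}, \code{mean_y},
#'   \code{mean_z} (1e-3 mm^2/s).
#' @export
measureRois <- function(maps, rois) {
  stopifnot(is(maps, "ADCMaps"), is(rois, "RoiSet"))
  d <- gridDims(maps)
  k <- sliceIndex(rois)
  if (k < 1 || k > d[3])
    stop(sprintf("ROI slice %d out of range [1, %d]", k, d[3]))
  regs <- roiRegions(rois)
  out <- vector("list", nrow(regs))
  for (i in seq_len(nrow(regs))) {
    lab <- regs$label[i]
    mem <- roiVoxels(regs$row[i], regs$col[i], regs$radius[i])
    if (any(mem$row < 1 | mem$row > d[1] | mem$col < 1 | mem$col > d[2]))
      stop(sprintf("ROI '%s' extends outside the grid", lab))
    idx <- cbind(mem$row, mem$col, k)
    valid <- validMask(maps)[idx]
    if (!any(valid))
      stop(sprintf("ROI '%s' contains no valid voxel", lab))
    idx <- idx[valid, , drop = FALSE]
    out[[i]] <- data.frame(
      label = lab, n_voxels = nrow(mem), n_valid = sum(valid),
      mean_x = mean(maps@adcX[idx]),
      mean_y = mean(maps@adcY[idx]),
      mean_z = mean(maps@adcZ[idx])
    )
  }
  do.call(rbind, out)
}

## internal: integer voxels of a closed disc
roiVoxels <- function(crow, ccol, radius) {
  r <- ceiling(radius)
  rows <- (round(crow) - r):(round(crow) + r)
  cols <- (round(ccol) - r):(round(ccol) + r)
  g <- expand.grid(row = rows, col = cols)
  g[(g$row - crow)^2 + (g$col - ccol)^2 <= radius^2, , drop = FALSE]
}

#' The ALPS index
#'
#' The ratio of perivascular-direction (x-axis) diffusivity to
#' fiber-perpendicular diffusivity:
#' \deqn{\mathrm{index} = \frac{\mathrm{mean}(ADC_{x,proj}, ADC_{x,assoc})}
#'                             {\mathrm{mean}(ADC_{y,proj}, ADC_{z,assoc})}}
#' At the measured slice the perivascular space runs along x, perpendicular
#' to both the cranio-caudal projection fibers (whose perpendicular in-plane
#' axis is y) and the antero-posterior association fibers (perpendicular z);
#' values near 1 indicate no preferential perivascular diffusivity.
#'
#' @param adcxProj,adcxAssoc x-axis mean diffusivity in the projection- and
#'   association-fiber regions.
#' @param adcyProj y-axis mean diffusivity in the projection-fiber region.
#' @param adczAssoc z-axis mean diffusivity in the association-fiber region.
#' @return The dimensionless index.
#' @examples
#' alpsIndex(1.2, 1.0, 0.8, 0.6) # 1.5714...
#' @export
alpsIndex <- function(adcxProj, adcxAssoc, adcyProj, adczAssoc) {
  v <- c(adcxProj, adcxAssoc, adcyProj, adczAssoc)
  if (length(v) != 4L || !all(is.finite(v)))
    stop("all four mean diffusivities must be finite scalars")
  denom <- (adcyProj + adczAssoc) / 2
  if (denom <= 0) stop("degenerate denominator: mean(ADCy proj, ADCz assoc) <= 0")
  ((adcxProj + adcxAssoc) / 2) / denom
}

#' Measure one subject end to end
#'
#' Chains ADC computation, ROI measurement and the index formula for one
#' observer's ROI placement. Left and right regions of each fiber type are
#' averaged before the formula (bilateral mean); set
#' \code{perHemisphere = TRUE} to also obtain separate left and right
#' indices.
#'
#' @param study a \linkS4class{DiffusionStudy}.
#' @param rois the observer's \linkS4class{RoiSet}.
#' @param observerID observer identifier string.
#' @param perHemisphere also return per-hemisphere indices.
#' @return An \linkS4class{AlpsMeasurement}; with
#'   \code{perHemisphere = TRUE}, a list with elements \code{measurement},
#'   \code{left}, \code{right}.
#' @export
measureSubject <- function(study, rois, observerID = "A", perHemisphere = FALSE) {
  maps <- withStage("adc", computeADC(study))
  tab <- withStage("measure", measureRois(maps, rois))
  get <- function(lab, ax) tab[tab$label == lab, paste0("mean_", ax)]
  xProj <- (get("L_proj", "x") + get("R_proj", "x")) / 2
  xAssoc <- (get("L_assoc", "x") + get("R_assoc", "x")) / 2
  yProj <- (get("L_proj", "y") + get("R_proj", "y")) / 2
  zAssoc <- (get("L_assoc", "z") + get("R_assoc", "z")) / 2
  m <- new("AlpsMeasurement",
    adcxProj = xProj, adcxAssoc = xAssoc, adcyProj = yProj, adczAssoc = zAssoc,
    alpsIndex = alpsIndex(xProj, xAssoc, yProj, zAssoc),
    subjectID = subjectID(study), observerID = as.character(observerID)
  )
  if (!perHemisphere) return(m)
  side <- function(s) alpsIndex(get(paste0(s, "_proj"), "x"),
                                get(paste0(s, "_assoc"), "x"),
                                get(paste0(s, "_proj"), "y"),
                                get(paste0(s, "_assoc"), "z"))
  list(measurement = m, left = side("L"), right = side("R"))
}

## internal: rethrow stage errors with the stage named
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Combine observers into a per-subject mean index
#'
#' The final per-subject index is the arithmetic mean of the observers'
#' indices.
#'
#' @param measurements list of \linkS4class{AlpsMeasurement} (one or more
#'   observers per subject).
#' @return data.frame with columns \code{subject_id}, \code{index},
#'   \code{n_observers}.
#' @export
combineObservers <- function(measurements) {
  stopifnot(length(measurements) >= 1,
            all(vapply(measurements, is, logical(1), "AlpsMeasurement")))
  ids <- vapply(measurements, subjectID, character(1))
  vals <- vapply(measurements, indexValue, numeric(1))
  agg <- tapply(vals, ids, mean)
  cnt <- tapply(vals, ids, length)
  data.frame(subject_id = names(agg), index = as.numeric(agg),
             n_observers = as.integer(cnt), row.names = NULL)
}

#' Serialize measurements to CSV
#'
#' Columns: subject_id, observer_id, adcx_proj, adcx_assoc, adcy_proj,
#' adcz_assoc, alps_index. Values are written at full precision (17
#' significant digits) so identical runs give byte-identical files.
#'
#' @param measurements list of \linkS4class{AlpsMeasurement}.
#' @param file output CSV path.
#' @return Invisibly, \code{file}.
#' @export
writeMeasurements <- function(measurements, file) {
  rows <- lapply(measurements, function(m) {
    v <- roiMeans(m)
    data.frame(subject_id = subjectID(m), observer_id = observerID(m),
               adcx_proj = v[["adcx_proj"]], adcx_assoc = v[["adcx_assoc"]],
               adcy_proj = v[["adcy_proj"]], adcz_assoc = v[["adcz_assoc"]],
               alps_index = indexValue(m))
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
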