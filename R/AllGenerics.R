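## Accessor generics and show methods. Slots are never reached into from user
## code; these accessors are the supported surface.

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("bValue", function(x) standardGeneric("bValue"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname accessors
#' @export
setGeneric("observerID", function(x) standardGeneric("observerID"))
#' @rdname accessors
#' @export
setGeneric("subjectAge", function(x) standardGeneric("subjectAge"))
#' @rdname accessors
#' @export
setGeneric("signalVolume", function(x, axis) standardGeneric("signalVolume"))
#' @rdname accessors
#' @export
setGeneric("adcVolume", function(x, axis) standardGeneric("adcVolume"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("sliceIndex", function(x) standardGeneric("sliceIndex"))
#' @rdname accessors
#' @export
setGeneric("roiRegions", function(x) standardGeneric("roiRegions"))
#' @rdname accessors
#' @export
setGeneric("indexValue", function(x) standardGeneric("indexValue"))
#' @rdname accessors
#' @export
setGeneric("roiMeans", function(x) standardGeneric("roiMeans"))
#' @rdname accessors
#' @export
setGeneric("rgbArray", function(x) standardGeneric("rgbArray"))

#' Accessors for dwialps classes
#'
#' @param x an object of one of the package's S4 classes.
#' @param axis one of "x", "y", "z" (image axes).
#' @return The accessed component: dimensions, scalars, arrays or data.frames
#'   as documented per class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("gridDims", "DiffusionStudy", function(x) dim(x@s0))
#' @rdname accessors
#' @export
setMethod("gridDims", "ADCMaps", function(x) dim(x@adcX))
#' @rdname accessors
#' @export
setMethod("bValue", "DiffusionStudy", function(x) x@bValue)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DiffusionStudy", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("subjectID", "DiffusionStudy", function(x) x@subjectID)
#' @rdname accessors
#' @export
setMethod("subjectID", "AlpsMeasurement", function(x) x@subjectID)
#' @rdname accessors
#' @export
setMethod("observerID", "AlpsMeasurement", function(x) x@observerID)
#' @rdname accessors
#' @export
setMethod("subjectAge", "DiffusionStudy", function(x) x@age)

#' @rdname accessors
#' @export
setMethod("signalVolume", "DiffusionStudy", function(x, axis = c("b0", "x", "y", "z")) {
  axis <- match.arg(axis)
  switch(axis, b0 = x@s0, x = x@sx, y = x@sy, z = x@sz)
})

#' @rdname accessors
#' @export
setMethod("adcVolume", "ADCMaps", function(x, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  switch(axis, x = x@adcX, y = x@adcY, z = x@adcZ)
})

#' @rdname accessors
#' @export
setMethod("validMask", "ADCMaps", function(x) x@validMask)
#' @rdname accessors
#' @export
setMethod("sliceIndex", "RoiSet", function(x) x@sliceIndex)
#' @rdname accessors
#' @export
setMethod("sliceIndex", "CompositeImage", function(x) x@sliceIndex)
#' @rdname accessors
#' @export
setMethod("roiRegions", "RoiSet", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("indexValue", "AlpsMeasurement", function(x) x@alpsIndex)
#' @rdname accessors
#' @export
setMethod("rgbArray", "CompositeImage", function(x) x@rgb)

#' @rdname accessors
#' @export
setMethod("roiMeans", "AlpsMeasurement", function(x) {
  c(adcx_proj = x@adcxProj, adcx_assoc = x@adcxAssoc,
    adcy_proj = x@adcyProj, adcz_assoc = x@adczAssoc)
})

setMethod("show", "DiffusionStudy", function(object) {
  d <- dim(object@s0)
  cat("DiffusionStudy '", object@subjectID, "'\n", sep = "")
  cat("  grids: ", paste(d, collapse = " x "),
      " (b=0 plus MPG x/y/z), b = ", object@bValue, " s/mm^2\n", sep = "")
  cat("  voxel size: ", paste(object@voxelSize, collapse = " x "), " mm",
      if (!is.na(object@age)) sprintf(", age %g y", object@age), "\n", sep = "")
})

setMethod("show", "ADCMaps", function(object) {
  d <- dim(object@adcX)
  cat("ADCMaps: ", paste(d, collapse = " x "),
      " per-axis diffusivity volumes (1e-3 mm^2/s)\n", sep = "")
  cat(sprintf("  valid voxels: %d / %d; negative ADCs retained: %d\n",
              sum(object@validMask), length(object@validMask), object@nNegative))
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet on slice", object@sliceIndex, "\n")
  print(object@regions, row.names = FALSE)
})

setMethod("show", "AlpsMeasurement", function(object) {
  cat(sprintf("AlpsMeasurement subject '%s', observer '%s'\n",
              object@subjectID, object@observerID))
  cat(sprintf("  ADCx(proj) %.4f  ADCx(assoc) %.4f  ADCy(proj) %.4f  ADCz(assoc) %.4f\n",
              object@adcxProj, object@adcxAssoc, object@adcyProj, object@adczAssoc))
  cat(sprintf("  ALPS index: %.4f\n", object@alpsIndex))
})

setMethod("show", "CompositeImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("CompositeImage slice %d: %d x %d, x=red y=green z=blue, adcRef %g\n",
              object@sliceIndex, d[1], d[2], object@adcRef))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec ", paste(object@dims, collapse = " x "),
      sprintf(" grid, b = %g s/mm^2, sigma = %g (SNR %s)\n",
              object@bValue, object@sigma,
              if (object@sigma > 0) format(object@s0 / object@sigma) else "Inf"),
      sep = "")
  for (nm in names(object@regions)) {
    cat(sprintf("  %-10s D = (%s) x 1e-3 mm^2/s\n", nm,
                paste(format(object@regions[[nm]]$D), collapse = ", ")))
  }
  cat(sprintf("  ground-truth ALPS index: %g\n", phantomTruthIndex(object)))
})

setMethod("show", "CohortSimSpec", function(object) {
  cat("CohortSimSpec:", sum(object@counts), "subjects, decade counts",
      paste(object@counts, collapse = "/"), "\n")
  cat(sprintf("  index(age) = %g - %g (age - %g)^2; subject SD %g, observer SD %g\n",
              object@peakValue, object@curvature, object@peakAge,
              object@subjectSD, object@observerSD))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult (%s), n = %d\n", object@model, object@n))
  co <- object@coefficients
  cat("  coefficients:", paste(sprintf("%s = %.6g", names(co), co), collapse = ", "), "\n")
  if (object@model == "linear") cat(sprintf("  r = %.4f\n", object@r))
  else {
    cat(sprintf("  R = %.4f", object@R))
    if (is.finite(object@vertexAge)) cat(sprintf(", vertex at %.1f y", object@vertexAge))
    cat("\n")
  }
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("AnovaResult: F = %.4g, p = %.4g over %d decade groups\n",
              object@fStatistic, object@pValue, nrow(object@groups)))
  sig <- object@pairwise[object@pairwise$significant, , drop = FALSE]
  cat(sprintf("  %d of %d pairwise contrasts significant (Tukey, 0.05)\n",
              nrow(sig), nrow(object@pairwise)))
})
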