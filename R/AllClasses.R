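#' @import methods
NULL

## Conventions used throughout the package
## ----------------------------------------
## Voxel grids are 3-D arrays indexed [row, col, slice], 1-based (native R
## indexing). "x", "y", "z" name the IMAGE axes: x = row (left-right),
## y = col (anterior-posterior), z = slice (cranio-caudal). Diffusivities are
## stored and reported in units of 1e-3 mm^2/s; b-values in s/mm^2. Masked-out
## voxels in ADC maps carry NA, never a silent zero.

#' DiffusionStudy: one subject's b=0 and three diffusion-weighted volumes
#'
#' Container for a single three-direction diffusion-weighted acquisition: a
#' b=0 volume and one diffusion-weighted volume per motion-probing gradient
#' (MPG) applied along each image axis. The MPG axes are assumed to coincide
#' with the image axes (gradients applied orthogonally to the imaging plane);
#' use [permuteAxes()] for data acquired with a different axis ordering.
#'
#' Class validity only enforces structural typing; scientific invariants
#' (matching grid dimensions, positive b-value, non-negative signals) are
#' checked by [validateStudy()], which reports violations rather than
#' throwing, so that malformed studies can be represented and diagnosed.
#'
#' @slot s0 3-D array, b=0 signal (arbitrary units).
#' @slot sx,sy,sz 3-D arrays, diffusion-weighted signal for MPG along the
#'   image x, y, z axes.
#' @slot bValue diffusion weighting in s/mm^2.
#' @slot voxelSize numeric(3), per-axis spacing in mm.
#' @slot subjectID character scalar.
#' @slot age age in years (\code{NA} if unknown).
#' @export
setClass("DiffusionStudy",
  representation(
    s0 = "array", sx = "array", sy = "array", sz = "array",
    bValue = "numeric", voxelSize = "numeric",
    subjectID = "character", age = "numeric"
  ),
  prototype(
    bValue = 1000, voxelSize = c(1, 1, 1),
    subjectID = "subject", age = NA_real_
  ),
  validity = function(object) {
    msgs <- character()
    for (nm in c("s0", "sx", "sy", "sz")) {
      if (length(dim(slot(object, nm))) != 3L)
        msgs <- c(msgs, sprintf("'%s' must be a 3-D array", nm))
    }
    if (length(object@bValue) != 1L) msgs <- c(msgs, "'bValue' must be length 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msgs <- c(msgs, "'voxelSize' must be 3 positive spacings (mm)")
    if (length(object@subjectID) != 1L) msgs <- c(msgs, "'subjectID' must be length 1")
    if (length(object@age) != 1L) msgs <- c(msgs, "'age' must be length 1")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a DiffusionStudy
#'
#' @param s0,sx,sy,sz 3-D signal arrays (b=0 and per-axis diffusion-weighted).
#' @param bValue diffusion weighting in s/mm^2 (default 1000).
#' @param voxelSize numeric(3) voxel spacing in mm.
#' @param subjectID subject identifier.
#' @param age subject age in years, or \code{NA}.
#' @return A \linkS4class{DiffusionStudy} object.
#' @examples
#' g <- array(1000, c(4, 4, 2))
#' DiffusionStudy(g, g * exp(-1), g * exp(-1), g * exp(-1))
#' @export
DiffusionStudy <- function(s0, sx, sy, sz, bValue = 1000,
                           voxelSize = c(1, 1, 1),
                           subjectID = "subject", age = NA_real_) {
  new("DiffusionStudy",
    s0 = s0, sx = sx, sy = sy, sz = sz,
    bValue = as.numeric(bValue), voxelSize = as.numeric(voxelSize),
    subjectID = as.character(subjectID), age = as.numeric(age)
  )
}

#' ADCMaps: per-axis apparent diffusion coefficient volumes
#'
#' Three co-registered scalar volumes holding the apparent diffusion
#' coefficient estimated along each image axis, in 1e-3 mm^2/s, plus a
#' validity mask. Voxels where the ADC is not computable (non-positive b=0 or
#' diffusion-weighted signal on any axis) are NA in all three maps and FALSE
#' in the mask. Negative ADC values (diffusion-weighted signal above b=0,
#' possible under noise) are retained, not zeroed; their count is kept in
#' \code{nNegative}.
#'
#' @slot adcX,adcY,adcZ 3-D arrays, ADC per axis (1e-3 mm^2/s; NA where
#'   invalid).
#' @slot validMask logical 3-D array.
#' @slot nNegative integer, number of retained negative ADC values across the
#'   three maps.
#' @export
setClass("ADCMaps",
  representation(
    adcX = "array", adcY = "array", adcZ = "array",
    validMask = "array", nNegative = "integer"
  ),
  validity = function(object) {
    d <- dim(object@adcX)
    if (length(d) != 3L) return("'adcX' must be a 3-D array")
    for (nm in c("adcY", "adcZ", "validMask")) {
      if (!identical(dim(slot(object, nm)), d))
        return(sprintf("'%s' dimensions differ from 'adcX'", nm))
    }
    if (!is.logical(object@validMask)) return("'validMask' must be logical")
    TRUE
  }
)

#' RoiSet: the four circular measurement regions on one axial slice
#'
#' Four labeled in-plane circular regions of interest on the axial slice
#' containing the body of the lateral ventricle: right and left projection
#' fiber areas (\code{R_proj}, \code{L_proj}) and right and left association
#' fiber areas (\code{R_assoc}, \code{L_assoc}). Centers are (row, col) voxel
#' coordinates (1-based); a voxel belongs to a region iff
#' (row - c_row)^2 + (col - c_col)^2 <= radius^2 (inclusive boundary).
#'
#' @slot sliceIndex 1-based axial slice index.
#' @slot regions data.frame with columns \code{label}, \code{row}, \code{col},
#'   \code{radius}; exactly the four labels above, pairwise disjoint discs.
#' @export
setClass("RoiSet",
  representation(sliceIndex = "integer", regions = "data.frame"),
  validity = function(object) {
    r <- object@regions
    need <- c("label", "row", "col", "radius")
    if (!all(need %in% names(r))) {
      return(sprintf("regions must have columns %s", paste(need, collapse = ", ")))
    }
    want <- c("R_proj", "L_proj", "R_assoc", "L_assoc")
    if (nrow(r) != 4L || anyDuplicated(r$label) || !setequal(r$label, want))
      return("regions must carry exactly the labels R_proj, L_proj, R_assoc, L_assoc")
    if (any(r$radius < 0)) return("radii must be non-negative")
    if (length(object@sliceIndex) != 1L || object@sliceIndex < 1L)
      return("'sliceIndex' must be a single index >= 1")
    ## pairwise disjointness of the closed discs
    for (i in 1:3) for (j in (i + 1):4) {
      d <- sqrt((r$row[i] - r$row[j])^2 + (r$col[i] - r$col[j])^2)
      if (d <= r$radius[i] + r$radius[j])
        return(sprintf("regions '%s' and '%s' overlap", r$label[i], r$label[j]))
    }
    TRUE
  }
)

#' Construct a RoiSet
#'
#' @param sliceIndex 1-based axial slice index.
#' @param regions data.frame with columns \code{label} (one each of
#'   \code{R_proj}, \code{L_proj}, \code{R_assoc}, \code{L_assoc}),
#'   \code{row}, \code{col} (center, voxels), \code{radius} (voxels).
#' @return A \linkS4class{RoiSet}.
#' @seealso [defaultRoiSet()] for the phantom-matched default placement.
#' @export
RoiSet <- function(sliceIndex, regions) {
  regions$label <- as.character(regions$label)
  new("RoiSet", sliceIndex = as.integer(sliceIndex),
      regions = regions[, c("label", "row", "col", "radius")])
}

#' AlpsMeasurement: four pooled ROI diffusivities and the ALPS index
#'
#' One observer's measurement for one subject: the bilaterally pooled mean
#' diffusivities entering the ALPS formula, and the index itself. Validity
#' enforces that the stored index is exactly recomputable from the stored
#' means via [alpsIndex()].
#'
#' @slot adcxProj,adcxAssoc,adcyProj,adczAssoc mean diffusivities
#'   (1e-3 mm^2/s).
#' @slot alpsIndex dimensionless ratio.
#' @slot subjectID,observerID character scalars.
#' @export
setClass("AlpsMeasurement",
  representation(
    adcxProj = "numeric", adcxAssoc = "numeric",
    adcyProj = "numeric", adczAssoc = "numeric",
    alpsIndex = "numeric", subjectID = "character", observerID = "character"
  ),
  validity = function(object) {
    v <- c(object@adcxProj, object@adcxAssoc, object@adcyProj, object@adczAssoc)
    if (length(v) != 4L || !all(is.finite(v)))
      return("all four mean diffusivities must be finite scalars")
    recomputed <- ((object@adcxProj + object@adcxAssoc) / 2) /
      ((object@adcyProj + object@adczAssoc) / 2)
    if (!identical(recomputed, object@alpsIndex))
      return("stored alpsIndex is not recomputable from the stored means")
    TRUE
  }
)

#' CompositeImage: the x=red, y=green, z=blue directional slice
#'
#' A single axial slice rendered as an RGB triplet image: per-axis ADC scaled
#' by a reference diffusivity and clipped to [0, 1]. Invalid voxels render
#' black.
#'
#' @slot rgb numeric array (rows x cols x 3), channel values in [0, 1].
#' @slot sliceIndex 1-based slice index rendered.
#' @slot adcRef normalization reference diffusivity (1e-3 mm^2/s).
#' @export
setClass("CompositeImage",
  representation(rgb = "array", sliceIndex = "integer", adcRef = "numeric"),
  validity = function(object) {
    d <- dim(object@rgb)
    if (length(d) != 3L || d[3] != 3L) return("'rgb' must be rows x cols x 3")
    if (any(object@rgb < 0 | object@rgb > 1)) return("channel values must lie in [0, 1]")
    if (object@adcRef <= 0) return("'adcRef' must be positive")
    TRUE
  }
)

#' PhantomSpec: geometry, tensors and noise of a diffusion phantom
#'
#' Declarative description of a synthetic diffusion phantom: an isotropic
#' background, an isotropic CSF-like ventricle, and mirrored left/right
#' projection- and association-fiber blocks whose diffusion tensors are given
#' by their diagonals (principal axes aligned with the image axes — the
#' three-axis measurement is blind to off-diagonal terms). Projection fibers
#' run cranio-caudally (Dz maximal), association fibers antero-posteriorly
#' (Dy maximal); both share an x-axis perivascular diffusivity component.
#'
#' @slot dims integer(3) grid dimensions (rows, cols, slices).
#' @slot regions named list; each element a list with \code{box} (3x2 matrix
#'   of inclusive 1-based index ranges, rows = x/y/z) and \code{D}
#'   (numeric(3) tensor diagonal, 1e-3 mm^2/s). Names from
#'   \code{background, ventricle, proj_L, proj_R, assoc_L, assoc_R};
#'   \code{background} fills all voxels not claimed by another region.
#' @slot s0 numeric, b=0 signal amplitude (arbitrary units, shared).
#' @slot bValue diffusion weighting in s/mm^2.
#' @slot sigma Rician noise level (signal units; 0 = noiseless).
#' @export
setClass("PhantomSpec",
  representation(
    dims = "integer", regions = "list",
    s0 = "numeric", bValue = "numeric", sigma = "numeric"
  ),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
      return("'dims' must be three positive extents")
    if (object@bValue <= 0) return("'bValue' must be positive")
    if (object@sigma < 0) return("'sigma' must be non-negative")
    if (object@s0 <= 0) return("'s0' must be positive")
    nms <- names(object@regions)
    ok <- c("background", "ventricle", "proj_L", "proj_R", "assoc_L", "assoc_R")
    if (is.null(nms) || !all(nms %in% ok) || anyDuplicated(nms))
      return("region names must be unique and drawn from the documented set")
    if (!"background" %in% nms) return("a 'background' region is required")
    for (nm in nms) {
      reg <- object@regions[[nm]]
      if (!is.numeric(reg$D) || length(reg$D) != 3L || any(reg$D <= 0))
        return(sprintf("region '%s': tensor diagonal must be 3 positive values", nm))
      if (nm != "background") {
        b <- reg$box
        if (!is.matrix(b) || !identical(dim(b), c(3L, 2L)))
          return(sprintf("region '%s': 'box' must be a 3x2 index-range matrix", nm))
        if (any(b[, 1] > b[, 2]) || any(b[, 1] < 1) || any(b[, 2] > object@dims))
          return(sprintf("region '%s': box outside grid bounds", nm))
      }
    }
    if ("ventricle" %in% nms) {
      D <- object@regions$ventricle$D
      if (diff(range(D)) > 0) return("ventricle tensor must be isotropic")
    }
    ## ties allowed so the isotropic null phantom remains representable
    for (nm in intersect(c("proj_L", "proj_R"), nms)) {
      D <- object@regions[[nm]]$D
      if (D[3] < max(D)) return(sprintf("'%s': projection fibers need Dz maximal", nm))
    }
    for (nm in intersect(c("assoc_L", "assoc_R"), nms)) {
      D <- object@regions[[nm]]$D
      if (D[2] < max(D)) return(sprintf("'%s': association fibers need Dy maximal", nm))
    }
    ## pairwise non-overlap of explicit boxes
    boxes <- object@regions[setdiff(nms, "background")]
    kn <- names(boxes)
    if (length(boxes) > 1) {
      for (i in seq_len(length(boxes) - 1)) for (j in (i + 1):length(boxes)) {
        a <- boxes[[i]]$box; b <- boxes[[j]]$box
        overlap <- all(a[, 1] <= b[, 2] & b[, 1] <= a[, 2])
        if (overlap) return(sprintf("regions '%s' and '%s' overlap", kn[i], kn[j]))
      }
    }
    TRUE
  }
)

#' CohortSimSpec: generative model for a simulated cohort
#'
#' Subject counts per decade and a quadratic age-index model
#' \code{index(age) = peakValue - curvature * (age - peakAge)^2} with
#' inter-subject and inter-observer Gaussian noise.
#'
#' @slot counts integer(8), subjects per decade 10s..80s.
#' @slot peakAge,peakValue,curvature quadratic model parameters (years,
#'   index units, index units per year^2).
#' @slot subjectSD inter-subject noise SD (index units).
#' @slot observerSD inter-observer noise SD (index units).
#' @export
setClass("CohortSimSpec",
  representation(
    counts = "integer", peakAge = "numeric", peakValue = "numeric",
    curvature = "numeric", subjectSD = "numeric", observerSD = "numeric"
  ),
  validity = function(object) {
    if (length(object@counts) != 8L || any(object@counts < 1L))
      return("'counts' must be 8 positive decade counts (10s..80s)")
    if (object@peakAge < 10 || object@peakAge > 89)
      return("'peakAge' must lie in [10, 89]")
    if (object@subjectSD < 0 || object@observerSD < 0)
      return("noise SDs must be non-negative")
    TRUE
  }
)

#' RegressionResult: a fitted age-index regression
#'
#' @slot model "linear" or "quadratic".
#' @slot coefficients named numeric: intercept, age, (age^2).
#' @slot r signed Pearson correlation (linear fits; NA for quadratic).
#' @slot R multiple correlation, sqrt of the coefficient of determination.
#' @slot vertexAge fitted peak age -b1/(2 b2) for a concave quadratic, else NA.
#' @slot band data.frame (age, fit, lwr, upr): two-sided 95% confidence band
#'   over the observed age range.
#' @slot n number of records used.
#' @export
setClass("RegressionResult",
  representation(
    model = "character", coefficients = "numeric", r = "numeric",
    R = "numeric", vertexAge = "numeric", band = "data.frame", n = "integer"
  ),
  validity = function(object) {
    if (!object@model %in% c("linear", "quadratic")) return("unknown model type")
    if (is.finite(object@r) && abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
    if (is.finite(object@R) && object@R < 0) return("R must be non-negative")
    TRUE
  }
)

#' AnovaResult: decade-wise one-way ANOVA with Tukey post-hoc table
#'
#' @slot groups data.frame of per-decade summaries: n, mean, and the boxplot
#'   five-number summary (type-7 quantiles) plus whiskers and outliers by the
#'   1.5 IQR rule.
#' @slot fStatistic one-way ANOVA F.
#' @slot pValue overall p.
#' @slot pairwise data.frame with one row per group pair: difference,
#'   Tukey-adjusted p, significance flag at the family-wise 0.05 level.
#' @slot outliers data.frame (decade, value) of boxplot outliers.
#' @export
setClass("AnovaResult",
  representation(
    groups = "data.frame", fStatistic = "numeric", pValue = "numeric",
    pairwise = "data.frame", outliers = "data.frame"
  ),
  validity = function(object) {
    k <- nrow(object@groups)
    if (k >= 2 && nrow(object@pairwise) != choose(k, 2))
      return("pairwise table must have one row per group pair")
    TRUE
  }
)
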