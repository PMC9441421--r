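#' Compute per-axis ADC maps from a three-direction study
#'
#' Applies the single-b monoexponential estimator voxelwise per axis:
#' \deqn{ADC_i = \ln(S_0 / S_i) / b}
#' reported in 1e-3 mm^2/s. With only b = 0 and one non-zero shell along each
#' of three axis-aligned gradients, no tensor fit is possible (or needed);
#' each axis is inverted independently.
#'
#' Voxels where the b=0 signal or any axis signal is non-positive are masked
#' (NA in all three maps, FALSE in the mask) rather than clamped — clamping
#' would silently bias downstream ROI means. Negative ADCs (axis signal above
#' b=0, which Rician noise can produce) are retained and counted, not zeroed:
#' zeroing biases means upward in noisy background.
#'
#' @param study a \linkS4class{DiffusionStudy}; must pass [validateStudy()].
#' @return An \linkS4class{ADCMaps}. If no voxel is computable a warning
#'   ("empty mask") is raised, not an error.
#' @examples
#' g <- array(1000, c(4, 4, 2))
#' a <- g * exp(-1)
#' maps <- computeADC(DiffusionStudy(g, a, a, a, bValue = 1000))
#' adcVolume(maps, "x")[1, 1, 1] # 1.0 (x 1e-3 mm^2/s)
#' @export
computeADC <- function(study) {
  rep <- validateStudy(study)
  if (!rep$pass)
    stop("invalid study: ", paste(rep$violations, collapse = "; "))
  s0 <- study@s0
  mask <- s0 > 0 & study@sx > 0 & study@sy > 0 & study@sz > 0
  scale <- 1000 / study@bValue # mm^2/s -> 1e-3 mm^2/s
  perAxis <- function(si) {
    adc <- array(NA_real_, dim(s0))
    adc[mask] <- log(s0[mask] / si[mask]) * scale
    adc
  }
  adcX <- perAxis(study@sx)
  adcY <- perAxis(study@sy)
  adcZ <- perAxis(study@sz)
  nNeg <- sum(adcX < 0, na.rm = TRUE) + sum(adcY < 0, na.rm = TRUE) +
    sum(adcZ < 0, na.rm = TRUE)
  if (!any(mask)) warning("empty mask: no voxel had computable ADC")
  new("ADCMaps", adcX = adcX, adcY = adcY, adcZ = adcZ,
      validMask = mask, nNegative = as.integer(nNeg))
}

#' Summary statistics of ADC maps within a mask
#'
#' Per-axis mean, sample standard deviation (n - 1 denominator) and count of
#' valid voxels among the masked voxels.
#'
#' @param maps an \linkS4class{ADCMaps}.
#' @param mask logical array, same dimensions as the maps.
#' @return data.frame with columns \code{axis}, \code{mean}, \code{sd},
#'   \code{n_valid}.
#' @export
adcSummary <- function(maps, mask) {
  stopifnot(is(maps, "ADCMaps"))
  if (!identical(dim(mask), gridDims(maps)))
    stop("mask dimensions differ from the ADC maps")
  if (!any(mask)) stop("empty region")
  do.call(rbind, lapply(c("x", "y", "z"), function(ax) {
    v <- adcVolume(maps, ax)[mask]
    v <- v[!is.na(v)]
    data.frame(axis = ax,
               mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n_valid = length(v))
  }))
}
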