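#' Render the directional RGB composite for one axial slice
#'
#' Maps per-axis diffusivity to color — x axis = red, y axis = green,
#' z axis = blue — so that the projection-fiber area (diffusivity dominant
#' along z) appears blue-dominant and the association-fiber area (dominant
#' along y) green-dominant, which is what locating the two measurement areas
#' requires. Each channel is the axis ADC divided by a fixed reference
#' diffusivity \code{adcRef} and clipped to [0, 1]; no eigen-decomposition is
#' involved (none exists for three axis-aligned gradients). Invalid voxels
#' render black.
#'
#' @param maps an \linkS4class{ADCMaps}.
#' @param sliceIndex 1-based axial slice to render.
#' @param adcRef reference diffusivity for normalization, 1e-3 mm^2/s
#'   (default 2.0, above typical white-matter diffusivity so that parenchyma
#'   stays unsaturated).
#' @return A \linkS4class{CompositeImage}.
#' @export
renderComposite <- function(maps, sliceIndex, adcRef = 2.0) {
  stopifnot(is(maps, "ADCMaps"))
  d <- gridDims(maps)
  if (adcRef <= 0) stop("'adcRef' must be positive")
  if (sliceIndex < 1 || sliceIndex > d[3])
    stop(sprintf("slice %d out of range [1, %d]", sliceIndex, d[3]))
  rgb <- array(0, c(d[1], d[2], 3L))
  for (k in 1:3) {
    ch <- adcVolume(maps, c("x", "y", "z")[k])[, , sliceIndex]
    ch <- pmin(pmax(ch / adcRef, 0), 1)
    ch[is.na(ch)] <- 0
    rgb[, , k] <- ch
  }
  new("CompositeImage", rgb = rgb, sliceIndex = as.integer(sliceIndex),
      adcRef = adcRef)
}

#' Write a composite image as an 8-bit PNG
#'
#' Channels are quantized round-half-up, \code{floor(255 v + 0.5)}, so that
#' output files are bit-reproducible.
#'
#' @param image a \linkS4class{CompositeImage}.
#' @param file output path (.png).
#' @return Invisibly, \code{file}.
#' @export
writeComposite <- function(image, file) {
  stopifnot(is(image, "CompositeImage"))
  q <- floor(rgbArray(image) * 255 + 0.5) / 255
  png::writePNG(q, file)
  invisible(file)
}

#' Suggest the axial slice containing the lateral-ventricle body
#'
#' Advisory helper for ROI placement: returns the axial slice with the
#' largest in-slice area of CSF-like voxels (mean ADC across the three axes
#' above \code{csfThreshold}) restricted to a central in-plane band, since
#' the ventricle body is medially located. Ties break to the lowest slice
#' index. The measured slice always comes from the \linkS4class{RoiSet};
#' this function only proposes one.
#'
#' @param maps an \linkS4class{ADCMaps}.
#' @param csfThreshold CSF diffusivity threshold, 1e-3 mm^2/s (default 2.0).
#' @param band fraction of the in-plane extent, centered, searched for CSF
#'   (default 0.5).
#' @return 1-based slice index.
#' @export
suggestSlice <- function(maps, csfThreshold = 2.0, band = 0.5) {
  stopifnot(is(maps, "ADCMaps"))
  d <- gridDims(maps)
  meanADC <- (maps@adcX + maps@adcY + maps@adcZ) / 3
  central <- function(n) {
    half <- floor(n * band / 2)
    mid <- (n + 1) / 2
    max(1L, ceiling(mid - half)):min(n, floor(mid + half))
  }
  rows <- central(d[1]); cols <- central(d[2])
  csf <- !is.na(meanADC) & meanADC > csfThreshold
  area <- vapply(seq_len(d[3]), function(k) sum(csf[rows, cols, k]), integer(1))
  if (all(area == 0L)) stop("no ventricle candidate: no CSF-like voxels found")
  which.max(area) # which.max takes the first (lowest) maximum
}
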