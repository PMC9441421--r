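## NIfTI-1 and sidecar I/O. Volumes travel as .nii.gz via RNifti; per-study
## acquisition metadata (b-value, subject id, age) lives in a YAML sidecar
## because NIfTI-1 has no standard slot for diffusion weighting.
##
## File layout for a study with prefix P under directory dir/:
##   P_b0.nii.gz, P_dwi_x.nii.gz, P_dwi_y.nii.gz, P_dwi_z.nii.gz, P_meta.yaml
## Sidecar schema (YAML mapping):
##   subject_id: string; age: number or ~; b_value: s/mm^2;
##   voxel_size: [dx, dy, dz] in mm

#' Write a DiffusionStudy to NIfTI files plus a YAML sidecar
#'
#' @param study a \linkS4class{DiffusionStudy}.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix; defaults to the subject id.
#' @return Invisibly, the character vector of files written.
#' @seealso [readDiffusionStudy()] for the inverse.
#' @export
writeDiffusionStudy <- function(study, dir, prefix = subjectID(study)) {
  stopifnot(is(study, "DiffusionStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vols <- c(b0 = "s0", dwi_x = "sx", dwi_y = "sy", dwi_z = "sz")
  files <- character()
  for (tag in names(vols)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, tag))
    img <- RNifti::asNifti(slot(study, vols[[tag]]))
    RNifti::pixdim(img) <- study@voxelSize
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  meta <- file.path(dir, sprintf("%s_meta.yaml", prefix))
  yaml::write_yaml(list(
    subject_id = study@subjectID,
    age = if (is.na(study@age)) NULL else study@age,
    b_value = study@bValue,
    voxel_size = as.numeric(study@voxelSize)
  ), meta)
  invisible(c(files, meta))
}

## internal: read a NIfTI volume as a plain 3-D array (strip niftiImage class)
readVolumeArray <- function(f) {
  if (!file.exists(f)) stop("input volume not found: ", f)
  img <- RNifti::readNifti(f)
  array(as.numeric(img), dim(img)[1:3])
}

#' Read a DiffusionStudy from NIfTI files plus a YAML sidecar
#'
#' @param dir directory holding the files written by [writeDiffusionStudy()].
#' @param prefix the filename prefix used at write time.
#' @return A \linkS4class{DiffusionStudy}.
#' @export
readDiffusionStudy <- function(dir, prefix) {
  pick <- function(tag)
    readVolumeArray(file.path(dir, sprintf("%s_%s.nii.gz", prefix, tag)))
  metaFile <- file.path(dir, sprintf("%s_meta.yaml", prefix))
  if (!file.exists(metaFile)) stop("missing sidecar: ", metaFile)
  meta <- yaml::read_yaml(metaFile)
  DiffusionStudy(
    s0 = pick("b0"), sx = pick("dwi_x"), sy = pick("dwi_y"), sz = pick("dwi_z"),
    bValue = meta$b_value,
    voxelSize = as.numeric(meta$voxel_size),
    subjectID = meta$subject_id,
    age = if (is.null(meta$age)) NA_real_ else meta$age
  )
}

#' Write ADC maps and the validity mask as NIfTI volumes
#'
#' Writes \code{<prefix>_adc_x/y/z.nii.gz} (NA-masked voxels stored as NaN)
#' and \code{<prefix>_adc_mask.nii.gz} (1 = valid).
#'
#' @param maps an \linkS4class{ADCMaps}.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @param voxelSize numeric(3) spacing in mm for the headers.
#' @return Invisibly, the files written.
#' @export
writeADCMaps <- function(maps, dir, prefix = "adc", voxelSize = c(1, 1, 1)) {
  stopifnot(is(maps, "ADCMaps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- list(adc_x = maps@adcX, adc_y = maps@adcY, adc_z = maps@adcZ,
              adc_mask = maps@validMask + 0)
  files <- character()
  for (tag in names(out)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, tag))
    img <- RNifti::asNifti(out[[tag]])
    RNifti::pixdim(img) <- voxelSize
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read ADC maps written by [writeADCMaps()]
#'
#' @param dir directory holding the volumes.
#' @param prefix filename prefix used at write time.
#' @return An \linkS4class{ADCMaps}. The negative-ADC count is recomputed
#'   from the read volumes.
#' @export
readADCMaps <- function(dir, prefix = "adc") {
  pick <- function(tag)
    readVolumeArray(file.path(dir, sprintf("%s_%s.nii.gz", prefix, tag)))
  mask <- pick("adc_mask") > 0.5
  fix <- function(a) { a[!mask] <- NA_real_; a }
  adcX <- fix(pick("adc_x")); adcY <- fix(pick("adc_y")); adcZ <- fix(pick("adc_z"))
  nNeg <- sum(adcX < 0, na.rm = TRUE) + sum(adcY < 0, na.rm = TRUE) +
    sum(adcZ < 0, na.rm = TRUE)
  new("ADCMaps", adcX = adcX, adcY = adcY, adcZ = adcZ,
      validMask = mask, nNegative = as.integer(nNeg))
}

#' Read or write an ROI configuration
#'
#' ROI files are YAML with schema: \code{slice: <int>} and \code{regions:},
#' a mapping from each label (\code{R_proj}, \code{L_proj}, \code{R_assoc},
#' \code{L_assoc}) to \code{\{row, col, radius\}} in voxel units.
#'
#' @param file path to the YAML file.
#' @return \code{readRoiSet} returns a \linkS4class{RoiSet}.
#' @export
readRoiSet <- function(file) {
  if (!file.exists(file)) stop("ROI file not found: ", file)
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$slice) || is.null(cfg$regions))
    stop("ROI file must define 'slice' and 'regions'")
  regs <- do.call(rbind, lapply(names(cfg$regions), function(lab) {
    r <- cfg$regions[[lab]]
    data.frame(label = lab, row = r$row, col = r$col, radius = r$radius)
  }))
  RoiSet(cfg$slice, regs)
}

#' @rdname readRoiSet
#' @param rois a \linkS4class{RoiSet} to serialize.
#' @export
writeRoiSet <- function(rois, file) {
  stopifnot(is(rois, "RoiSet"))
  r <- roiRegions(rois)
  regions <- setNames(lapply(seq_len(nrow(r)), function(i) {
    list(row = r$row[i], col = r$col[i], radius = r$radius[i])
  }), r$label)
  yaml::write_yaml(list(slice = sliceIndex(rois), regions = regions), file)
  invisible(file)
}
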