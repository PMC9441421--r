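#' Monoexponential diffusion-weighted signal
#'
#' The tensor signal model underlying per-axis ADC mapping: for a gradient
#' along image axis i, \eqn{S_i = S_0 \exp(-b D_i)} with \eqn{D_i} the
#' corresponding diagonal entry of the diffusion tensor.
#'
#' @param D numeric(3) tensor diagonal (Dx, Dy, Dz), 1e-3 mm^2/s.
#' @param axis one of "x", "y", "z".
#' @param s0 b=0 signal amplitude.
#' @param b diffusion weighting, s/mm^2.
#' @return The attenuated signal.
#' @examples
#' tensorSignal(c(1.0, 1.0, 1.0), "x", 1000, 1000) # 1000 * exp(-1)
#' @export
tensorSignal <- function(D, axis = c("x", "y", "z"), s0, b) {
  axis <- match.arg(axis)
  stopifnot(length(D) == 3L, all(D > 0), s0 > 0, b >= 0)
  Di <- D[[match(axis, c("x", "y", "z"))]]
  s0 * exp(-b * Di * 1e-3)
}

#' Default phantom geometry and tensors
#'
#' A 64 x 64 x 32 grid mimicking the measurement layout at cartoon fidelity:
#' an isotropic CSF-like ventricle box in the center (slices 13-21), with
#' mirrored projection-fiber blocks adjacent-lateral and association-fiber
#' blocks further lateral on each side, all embedded in isotropic
#' white-matter-like background.
#'
#' Tensor presets (1e-3 mm^2/s):
#' \describe{
#'   \item{default}{proj D = (1.2, 0.4, 1.4), assoc D = (1.2, 1.4, 0.4);
#'     ground-truth index (1.2 + 1.2) / (0.4 + 0.4) = 3.0. A sharply
#'     anisotropic configuration whose round-number ground truth makes
#'     end-to-end checks transparent.}
#'   \item{low_perivascular}{as default but Dx = 0.8 in both fiber regions;
#'     index 2.0.}
#'   \item{realistic}{proj D = (0.9, 0.6, 1.3), assoc D = (0.9, 1.3, 0.6);
#'     index 1.5, inside the range typically reported for healthy adults.}
#'   \item{isotropic}{all fiber-region tensors (0.8, 0.8, 0.8); index 1.0,
#'     the no-preferential-diffusivity null.}
#' }
#'
#' @param preset tensor preset name, see Details.
#' @param sigma Rician noise level in signal units (s0 is 1000, so
#'   \code{sigma = 50} gives SNR 20). Default 0 (noiseless).
#' @param dims grid dimensions.
#' @return A \linkS4class{PhantomSpec}.
#' @export
defaultPhantomSpec <- function(preset = c("default", "low_perivascular",
                                          "realistic", "isotropic"),
                               sigma = 0, dims = c(64L, 64L, 32L)) {
  preset <- match.arg(preset)
  tensors <- switch(preset,
    default = list(proj = c(1.2, 0.4, 1.4), assoc = c(1.2, 1.4, 0.4)),
    low_perivascular = list(proj = c(0.8, 0.4, 1.4), assoc = c(0.8, 1.4, 0.4)),
    realistic = list(proj = c(0.9, 0.6, 1.3), assoc = c(0.9, 1.3, 0.6)),
    isotropic = list(proj = c(0.8, 0.8, 0.8), assoc = c(0.8, 0.8, 0.8))
  )
  box <- function(x, y, z) matrix(c(x, y, z), nrow = 3, byrow = TRUE)
  ys <- c(23, 42); zs <- c(13, 21)
  new("PhantomSpec",
    dims = as.integer(dims),
    regions = list(
      background = list(D = c(0.8, 0.8, 0.8)),
      ventricle = list(box = box(c(27, 38), ys, zs), D = c(3.0, 3.0, 3.0)),
      proj_L = list(box = box(c(17, 24), ys, zs), D = tensors$proj),
      proj_R = list(box = box(c(41, 48), ys, zs), D = tensors$proj),
      assoc_L = list(box = box(c(7, 14), ys, zs), D = tensors$assoc),
      assoc_R = list(box = box(c(51, 58), ys, zs), D = tensors$assoc)
    ),
    s0 = 1000, bValue = 1000, sigma = sigma
  )
}

#' Default ROI placement for the default phantom geometry
#'
#' Circles of radius 3 centered inside each fiber block on slice 17 (the
#' central ventricle-body slice of [defaultPhantomSpec()]).
#'
#' @param radius ROI radius in voxels (default 3).
#' @return A \linkS4class{RoiSet}.
#' @export
defaultRoiSet <- function(radius = 3) {
  RoiSet(17L, data.frame(
    label = c("L_proj", "R_proj", "L_assoc", "R_assoc"),
    row = c(21, 44, 11, 54),
    col = c(32, 32, 32, 32),
    radius = radius
  ))
}

#' Closed-form ground-truth ALPS index of a phantom
#'
#' The index implied directly by the generating tensors:
#' mean(Dx over projection regions, Dx over association regions) /
#' mean(Dy over projection regions, Dz over association regions). Left and
#' right tensors of each fiber type are averaged first (they are equal in
#' the shipped presets). Independent of grid, geometry, and noise.
#'
#' @param spec a \linkS4class{PhantomSpec} containing the four fiber regions.
#' @return The ground-truth index.
#' @export
phantomTruthIndex <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  D <- function(nm) spec@regions[[nm]]$D
  need <- c("proj_L", "proj_R", "assoc_L", "assoc_R")
  if (!all(need %in% names(spec@regions)))
    stop("spec lacks the four fiber regions")
  dxProj <- (D("proj_L")[1] + D("proj_R")[1]) / 2
  dxAssoc <- (D("assoc_L")[1] + D("assoc_R")[1]) / 2
  dyProj <- (D("proj_L")[2] + D("proj_R")[2]) / 2
  dzAssoc <- (D("assoc_L")[3] + D("assoc_R")[3]) / 2
  alpsIndex(dxProj, dxAssoc, dyProj, dzAssoc)
}

#' Generate a diffusion phantom study
#'
#' Renders the spec into a \linkS4class{DiffusionStudy}: voxelwise
#' monoexponential signals per region, then Rician noise
#' \eqn{|s + n_1 + i\, n_2|} with \eqn{n_1, n_2 \sim N(0, \sigma)} applied
#' independently to the b=0 and each diffusion-weighted volume. All
#' randomness flows from \code{seed}; the same seed reproduces the volumes
#' bit for bit.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer RNG seed (used only when \code{sigma > 0}).
#' @param subjectID subject identifier for the generated study.
#' @return list with \code{study} (the \linkS4class{DiffusionStudy}),
#'   \code{truth} (region tensors and the closed-form index) and
#'   \code{labels} (integer region-label volume, 0 = background).
#' @export
generatePhantom <- function(spec, seed = 1L, subjectID = "phantom") {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@dims
  labels <- array(0L, d)
  regionNames <- setdiff(names(spec@regions), "background")
  Dx <- array(spec@regions$background$D[1], d)
  Dy <- array(spec@regions$background$D[2], d)
  Dz <- array(spec@regions$background$D[3], d)
  for (i in seq_along(regionNames)) {
    nm <- regionNames[i]
    b <- spec@regions[[nm]]$box
    ix <- b[1, 1]:b[1, 2]; iy <- b[2, 1]:b[2, 2]; iz <- b[3, 1]:b[3, 2]
    labels[ix, iy, iz] <- i
    D <- spec@regions[[nm]]$D
    Dx[ix, iy, iz] <- D[1]; Dy[ix, iy, iz] <- D[2]; Dz[ix, iy, iz] <- D[3]
  }
  att <- function(Dax) spec@s0 * exp(-spec@bValue * Dax * 1e-3)
  s0 <- array(spec@s0, d)
  sx <- att(Dx); sy <- att(Dy); sz <- att(Dz)
  if (spec@sigma > 0) {
    set.seed(as.integer(seed))
    rice <- function(s) {
      n <- length(s)
      sqrt((s + stats::rnorm(n, 0, spec@sigma))^2 +
             stats::rnorm(n, 0, spec@sigma)^2)
    }
    s0 <- array(rice(s0), d); sx <- array(rice(sx), d)
    sy <- array(rice(sy), d); sz <- array(rice(sz), d)
  }
  truth <- list(
    tensors = lapply(spec@regions, `[[`, "D"),
    alps_index = phantomTruthIndex(spec)
  )
  list(
    study = DiffusionStudy(s0, sx, sy, sz, bValue = spec@bValue,
                           subjectID = subjectID),
    truth = truth,
    labels = labels
  )
}

#' Boolean mask of one phantom region
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param region region name, e.g. "proj_L".
#' @return logical array over the grid.
#' @export
phantomRegionMask <- function(spec, region) {
  stopifnot(is(spec, "PhantomSpec"), region %in% names(spec@regions))
  m <- array(FALSE, spec@dims)
  if (region == "background") {
    for (nm in setdiff(names(spec@regions), "background")) {
      b <- spec@regions[[nm]]$box
      m[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]] <- TRUE
    }
    return(!m)
  }
  b <- spec@regions[[region]]$box
  m[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]] <- TRUE
  m
}
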