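#' Validate a DiffusionStudy
#'
#' Checks the scientific invariants of a study — identical grid dimensions
#' across the four volumes, a positive b-value, non-negative signals — and
#' returns an itemized report instead of throwing, so malformed inputs can be
#' inspected.
#'
#' @param study a \linkS4class{DiffusionStudy}.
#' @return A list with elements \code{pass} (logical) and \code{violations}
#'   (character vector, empty when the study is well formed).
#' @examples
#' g <- array(1000, c(4, 4, 2))
#' validateStudy(DiffusionStudy(g, g, g, g))$pass
#' @export
validateStudy <- function(study) {
  stopifnot(is(study, "DiffusionStudy"))
  violations <- character()
  d0 <- dim(study@s0)
  for (nm in c("sx", "sy", "sz")) {
    if (!identical(dim(slot(study, nm)), d0))
      violations <- c(violations, sprintf("shape mismatch: '%s' differs from 's0'", nm))
  }
  if (!is.finite(study@bValue) || study@bValue <= 0)
    violations <- c(violations, "non-positive b")
  for (nm in c("s0", "sx", "sy", "sz")) {
    v <- slot(study, nm)
    if (any(v < 0, na.rm = TRUE))
      violations <- c(violations, sprintf("negative signals in '%s'", nm))
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Decade label for an age
#'
#' Buckets an age into the ten-year generation labels "10s" through "80s"
#' by integer division. The supported range [10, 89] matches an enrollment
#' policy of completed white-matter myelination (over 10 years) up to the
#' late eighties.
#'
#' @param age age(s) in years (integer-valued).
#' @return Character vector of decade labels, e.g. \code{"40s"}.
#' @examples
#' decadeOf(47) # "40s"
#' decadeOf(c(12, 84))
#' @export
decadeOf <- function(age) {
  if (any(!is.finite(age)) || any(age < 10) || any(age > 89))
    stop("age out of supported range [10, 89]")
  paste0((age %/% 10) * 10, "s")
}

#' Permute the gradient-to-image axis assignment
#'
#' The package assumes the motion-probing gradients were applied along the
#' image axes, so the x/y/z diffusion-weighted volumes map directly to image
#' rows/cols/slices. For data acquired with a different assignment, this
#' relabels the three diffusion-weighted volumes.
#'
#' @param study a \linkS4class{DiffusionStudy}.
#' @param order integer(3): which acquired volume supplies the image x, y, z
#'   axis, e.g. \code{c(2, 1, 3)} swaps x and y.
#' @return A relabeled \linkS4class{DiffusionStudy}.
#' @export
permuteAxes <- function(study, order) {
  stopifnot(is(study, "DiffusionStudy"),
            length(order) == 3L, setequal(order, 1:3))
  vols <- list(study@sx, study@sy, study@sz)
  initialize(study, sx = vols[[order[1]]], sy = vols[[order[2]]],
             sz = vols[[order[3]]])
}

#' Assemble a cohort table
#'
#' Builds the per-subject record table feeding the cohort statistics: the two
#' observers' ALPS indices, their mean (the final per-subject index), and the
#' decade label. The mean and decade columns are derived here so the table's
#' invariants hold by construction.
#'
#' @param subjectID character vector of subject identifiers.
#' @param age integer ages in years, within [10, 89].
#' @param indexA,indexB per-observer ALPS indices.
#' @return data.frame with columns \code{subject_id}, \code{age},
#'   \code{index_obs_a}, \code{index_obs_b}, \code{index} (observer mean) and
#'   \code{decade}.
#' @examples
#' makeCohortTable(c("s1", "s2"), c(34, 71), c(1.5, 1.3), c(1.6, 1.2))
#' @export
makeCohortTable <- function(subjectID, age, indexA, indexB) {
  n <- length(subjectID)
  stopifnot(length(age) == n, length(indexA) == n, length(indexB) == n)
  data.frame(
    subject_id = as.character(subjectID),
    age = as.integer(age),
    index_obs_a = as.numeric(indexA),
    index_obs_b = as.numeric(indexB),
    index = (as.numeric(indexA) + as.numeric(indexB)) / 2,
    decade = decadeOf(age),
    stringsAsFactors = FALSE
  )
}

## internal: assert a data.frame looks like a cohort table
assertCohortTable <- function(table, needObservers = FALSE) {
  need <- c("age", "index")
  if (needObservers) need <- c(need, "index_obs_a", "index_obs_b")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(table)
}
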