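#' Rigid-body motion quality control
#'
#' Head motion is summarized from 6-parameter rigid realignment tables
#' (3 rotations in radians, then 3 translations in mm per volume — the
#' MCFLIRT column order). Displacement between consecutive volumes is the
#' RMS displacement of all points of a sphere of radius `brain_radius_mm`
#' under the relative transform, computed with the closed-form
#' sphere-integral expression
#' \deqn{d_{RMS} = \sqrt{\tfrac{R^2}{5}\,\mathrm{Tr}(A^\top A) + t^\top t}}
#' where `A = M_rel[1:3,1:3] - I` and `t` is the relative translation.
#' For a pure translation the result equals its Euclidean norm regardless
#' of radius.
#'
#' @name motion_qc
NULL

rigid_matrix <- function(par) {
  if (length(par) != 6 || any(!is.finite(par))) {
    stop("each motion row must hold 6 finite parameters")
  }
  rx <- par[1]; ry <- par[2]; rz <- par[3]
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  M <- diag(4)
  M[1:3, 1:3] <- Rz %*% Ry %*% Rx
  M[1:3, 4] <- par[4:6]
  M
}

#' Per-volume relative RMS displacement
#'
#' @param params Matrix or data frame with one row per volume and six
#'   columns: rotations (rad) about x, y, z then translations (mm).
#' @param brain_radius_mm Radius of the sphere over which displacement is
#'   averaged (default 50 mm).
#' @return Numeric vector, one entry per volume; the first entry is 0.
#' @rdname motion_qc
#' @export
relative_rms_displacement <- function(params, brain_radius_mm = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("motion table must have 6 columns")
  n <- nrow(params)
  if (n < 1) stop("motion table must have at least one volume")
  out <- numeric(n)
  if (n == 1) return(out)
  M_prev <- rigid_matrix(params[1, ])
  for (i in 2:n) {
    M_i <- rigid_matrix(params[i, ])
    M_rel <- M_i %*% solve(M_prev)
    A <- M_rel[1:3, 1:3] - diag(3)
    t <- M_rel[1:3, 4]
    out[i] <- sqrt(brain_radius_mm^2 / 5 * sum(A * A) + sum(t * t))
    M_prev <- M_i
  }
  out
}

#' Mean relative displacement (MRD)
#'
#' @param rel Vector of per-volume relative RMS displacements, mm.
#' @return The arithmetic mean, mm.
#' @rdname motion_qc
#' @export
mean_relative_displacement <- function(rel) {
  if (length(rel) == 0 || any(!is.finite(rel))) {
    stop("relative displacement vector must be non-empty and finite")
  }
  mean(rel)
}

#' Scrub high-motion volumes
#'
#' Retains volumes whose relative RMS displacement does not exceed the
#' threshold; displacement strictly greater than the threshold removes the
#' volume. Pair reconciliation (removing the partner of a removed ASL
#' volume) is handled at the quantification stage.
#'
#' @param rel Per-volume relative RMS displacement, mm.
#' @param threshold Scrubbing threshold, mm (default 0.5).
#' @return Integer indices (1-based) of retained volumes.
#' @rdname motion_qc
#' @export
scrub_volumes <- function(rel, threshold = 0.5) {
  which(rel <= threshold)
}

#' Subject-level exclusion rule
#'
#' @param mrd Subject MRD, mm.
#' @param threshold Exclusion threshold, mm (default 0.5); MRD strictly
#'   greater than the threshold excludes the subject.
#' @return TRUE if the subject should be excluded.
#' @rdname motion_qc
#' @export
exclude_subject <- function(mrd, threshold = 0.5) {
  if (any(!is.finite(mrd))) stop("MRD must be finite")
  mrd > threshold
}

#' Motion QC summary for one subject
#'
#' @param params 6-column motion parameter table (one row per volume).
#' @param brain_radius_mm Sphere radius for the displacement metric, mm.
#' @param scrub_threshold Volume scrubbing threshold, mm.
#' @param exclude_threshold Subject exclusion threshold, mm.
#' @return List with `rel` (per-volume displacement), `mrd` (computed on the
#'   full series, before scrubbing), `retained` volume indices, and
#'   `excluded` flag.
#' @export
motion_qc_summary <- function(params, brain_radius_mm = 50,
                              scrub_threshold = 0.5,
                              exclude_threshold = 0.5) {
  rel <- relative_rms_displacement(params, brain_radius_mm)
  mrd <- mean_relative_displacement(rel)
  list(rel = rel, mrd = mrd,
       retained = scrub_volumes(rel, scrub_threshold),
       excluded = exclude_subject(mrd, exclude_threshold))
}
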