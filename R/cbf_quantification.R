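#' ASL quantification constants
#'
#' Constants of the single-compartment pCASL kinetic model. Times are stored
#' in seconds so that the factor of 6000 in [rcbf_from_asl()] yields
#' ml/100g/min directly.
#'
#' @param lambda_coeff Blood-brain partition coefficient, ml/g.
#' @param alpha pCASL labeling efficiency, dimensionless in (0, 1].
#' @param t1a Longitudinal relaxation time of arterial blood, seconds.
#' @param pld Post-labeling delay, seconds.
#' @param label_dur Labeling (bolus) duration, seconds.
#' @return A list of class `asl_constants`.
#' @export
asl_constants <- function(lambda_coeff = 0.9, alpha = 0.86,
                          t1a = 1.8, pld = 1.8, label_dur = 1.6) {
  vals <- c(lambda_coeff, alpha, t1a, pld, label_dur)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ASL constants must be positive and finite")
  }
  if (alpha > 1) stop("labeling efficiency alpha must be <= 1")
  structure(list(lambda_coeff = lambda_coeff, alpha = alpha, t1a = t1a,
                 pld = pld, label_dur = label_dur),
            class = "asl_constants")
}

#' Global CBF from phase-contrast artery fluxes
#'
#' Converts the summed blood flux through the four feeding arteries
#' (bilateral internal carotid and vertebral arteries) to global cerebral
#' blood flow: `100 * sum(flux) / (rho * brain_volume)`, where `rho` is the
#' brain tissue density.
#'
#' @param fluxes Numeric vector of per-artery fluxes, ml/min (typically
#'   length 4).
#' @param brain_volume Brain parenchyma volume (gray + white matter), mL.
#' @param rho Brain tissue density, g/mL (default 1.06).
#' @return Global CBF in ml/100g/min.
#' @export
global_cbf_from_pc <- function(fluxes, brain_volume, rho = 1.06) {
  if (!is.numeric(fluxes) || any(!is.finite(fluxes))) {
    stop("fluxes must be finite numeric")
  }
  if (any(fluxes < 0)) stop("fluxes must be non-negative")
  if (!is.finite(brain_volume) || brain_volume <= 0) {
    stop("brain_volume must be positive")
  }
  if (!is.finite(rho) || rho <= 0) stop("rho must be positive")
  100 * sum(fluxes) / (rho * brain_volume)
}

#' Mean control-minus-label difference image
#'
#' Averages the control minus label difference over the retained
#' control/label pairs. Scrubbing removes whole pairs: a pair is retained
#' only if both of its volumes survived motion scrubbing, so `retained_pairs`
#' indexes pairs, not volumes.
#'
#' @param control Numeric array with pairs along the last dimension
#'   (voxels... x n_pairs), or a voxel x n_pairs matrix.
#' @param label Array of the same shape holding label volumes.
#' @param retained_pairs Integer indices of pairs to keep (default all).
#' @return Voxel-wise mean difference, same spatial shape as one volume.
#' @export
compute_delta_m <- function(control, label, retained_pairs = NULL) {
  control <- as.array(control)
  label <- as.array(label)
  if (!identical(dim(control), dim(label))) {
    stop("control and label series must share dimensions")
  }
  nd <- length(dim(control))
  n_pairs <- dim(control)[nd]
  if (is.null(retained_pairs)) retained_pairs <- seq_len(n_pairs)
  retained_pairs <- as.integer(retained_pairs)
  if (length(retained_pairs) == 0) {
    stop("QC failure: no control/label pairs retained")
  }
  if (any(retained_pairs < 1 | retained_pairs > n_pairs)) {
    stop("retained_pairs out of range")
  }
  diff <- control - label
  vox_dim <- dim(control)[-nd]
  m <- matrix(diff, ncol = n_pairs)
  dm <- rowMeans(m[, retained_pairs, drop = FALSE])
  if (length(vox_dim) > 1) dim(dm) <- vox_dim
  dm
}

#' Regional CBF from the pCASL kinetic model
#'
#' Voxel-wise single-compartment quantification:
#' \deqn{rCBF = \frac{6000\,\lambda\,\Delta M\, e^{PLD/T_{1a}}}
#'   {2\,\alpha\,M_{b0}\,T_{1a}\,(1 - e^{-LabelDur/T_{1a}})}}
#' in ml/100g/min. Voxels whose equilibrium magnetization is non-positive
#' cannot be quantified and are dropped from the mask; the count of dropped
#' voxels is recorded.
#'
#' @param delta_m Voxel-wise mean control-label difference.
#' @param m0 Equilibrium magnetization image (same shape).
#' @param constants An [asl_constants()] object.
#' @param mask Logical/0-1 array of voxels to quantify (default: all).
#' @return A `cbf_map` list with `values`, `mask`, and `n_excluded`.
#' @export
rcbf_from_asl <- function(delta_m, m0, constants = asl_constants(),
                          mask = NULL) {
  stopifnot(inherits(constants, "asl_constants"))
  delta_m <- as.array(delta_m)
  m0 <- as.array(m0)
  if (!identical(dim(delta_m), dim(m0))) stop("delta_m and m0 shape mismatch")
  if (is.null(mask)) mask <- array(TRUE, dim(delta_m)) else mask <- as.array(mask) > 0
  bad <- mask & !(is.finite(m0) & m0 > 0)
  n_excluded <- sum(bad)
  if (n_excluded > 0) {
    warning(sprintf("%d voxels with non-positive M0 excluded from mask",
                    n_excluded))
    mask <- mask & !bad
  }
  scale <- with(constants,
    6000 * lambda_coeff * exp(pld / t1a) /
      (2 * alpha * t1a * (1 - exp(-label_dur / t1a))))
  values <- array(NA_real_, dim(delta_m))
  values[mask] <- scale * delta_m[mask] / m0[mask]
  cbf_map(values, mask, n_excluded = n_excluded)
}

#' Construct a CBF map container
#'
#' @param values Voxel array of CBF values, ml/100g/min.
#' @param mask Logical array marking analyzed voxels.
#' @param voxel_size_mm Isotropic voxel edge length, mm.
#' @param calibrated Whether the map has been PC-calibrated.
#' @param scale_factor Calibration scale factor applied (1 if none).
#' @param n_excluded Count of voxels dropped during quantification.
#' @return A list of class `cbf_map`.
#' @export
cbf_map <- function(values, mask = NULL, voxel_size_mm = 2,
                    calibrated = FALSE, scale_factor = 1, n_excluded = 0L) {
  values <- as.array(values)
  if (is.null(mask)) mask <- is.finite(values) else mask <- as.array(mask) > 0
  if (!identical(dim(values), dim(mask))) stop("values/mask shape mismatch")
  if (any(!is.finite(values[mask]))) stop("non-finite CBF inside mask")
  structure(list(values = values, mask = mask, voxel_size_mm = voxel_size_mm,
                 calibrated = calibrated, scale_factor = scale_factor,
                 n_excluded = as.integer(n_excluded)),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("CBF map: %s grid, %d masked voxels (%.1f mm)\n",
              paste(dim(x$values), collapse = "x"), sum(x$mask),
              x$voxel_size_mm))
  cat(sprintf("  mean %.2f, range [%.2f, %.2f] ml/100g/min%s\n",
              mean(v), min(v), max(v),
              if (x$calibrated) sprintf(", calibrated (x%.4f)", x$scale_factor)
              else ""))
  invisible(x)
}

#' Calibrate a regional CBF map against PC-derived global CBF
#'
#' Applies the scalar factor that makes the mask-averaged rCBF equal the
#' global CBF measured with phase-contrast MRI, absorbing subject-specific
#' labeling-efficiency and T1a deviations.
#'
#' @param map A [cbf_map()].
#' @param global_cbf Global CBF from [global_cbf_from_pc()], ml/100g/min.
#' @return The calibrated `cbf_map`; `scale_factor` records the multiplier.
#' @export
calibrate_rcbf <- function(map, global_cbf) {
  stopifnot(inherits(map, "cbf_map"))
  mu <- mean(map$values[map$mask])
  if (!is.finite(mu) || mu <= 0) stop("mask-mean CBF must be positive")
  s <- global_cbf / mu
  out <- map
  out$values[out$mask] <- out$values[out$mask] * s
  out$calibrated <- TRUE
  out$scale_factor <- map$scale_factor * s
  out
}

#' Test-retest ICC(2,1) between two CBF maps
#'
#' Two-way random-effects, absolute-agreement, single-measurement intraclass
#' correlation treating masked voxels as targets and the two scans as
#' repeated measurements, with the F-distribution 95% confidence interval.
#'
#' @param map1,map2 `cbf_map` objects (or numeric arrays) on a shared mask.
#' @param mask Optional mask overriding the maps' own.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `n_voxels`.
#' @export
icc_test_retest <- function(map1, map2, mask = NULL, conf_level = 0.95) {
  v1 <- if (inherits(map1, "cbf_map")) map1 else cbf_map(map1)
  v2 <- if (inherits(map2, "cbf_map")) map2 else cbf_map(map2)
  if (is.null(mask)) mask <- v1$mask & v2$mask else mask <- as.array(mask) > 0
  x <- cbind(v1$values[mask], v2$values[mask])
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2) stop("need at least 2 voxels for ICC")
  # two-way ANOVA mean squares (targets = voxels, raters = scans)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw & Wong (1996) F-based interval for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v_num <- (a * msc + b * mse)^2
  v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  v <- v_num / v_den
  alpha <- 1 - conf_level
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, n_voxels = n)
}
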