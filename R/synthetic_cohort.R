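#' Synthetic infant CBF cohort generator
#'
#' Generates a self-contained synthetic infant cohort with known ground
#' truth: subject covariates (age, sex, head motion, SES), voxel-wise rCBF
#' maps on a small 3D grid partitioned into three spatial clusters
#' (limbic core, sensorimotor shell, frontoparietal rim) with
#' cluster-specific biphasic trajectories, phase-contrast artery fluxes and
#' pCASL control/label series consistent with the quantification equations,
#' and Bayley-like behavior scores correlated with age-adjusted regional
#' CBF.
#'
#' @name synthetic_cohort
NULL

default_cluster_params <- function() {
  data.frame(
    cluster = c("limbic", "sensorimotor", "frontoparietal"),
    intercept = c(23.4, 15.2, 10.4),
    slope1 = c(3.64, 6.91, 3.65),
    psi = c(6.71, 7.69, 10.36),
    slope2 = c(0.06, 0.02, 2.84),
    stringsAsFactors = FALSE
  )
}

#' Generator configuration
#'
#' @param n_subjects Cohort size (default 76, the regional cohort; use 119
#'   for global-CBF cohorts).
#' @param grid_shape 3D grid dimensions (default 20 x 24 x 20).
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @param cluster_fractions Named proportions of masked voxels per cluster;
#'   must sum to 1.
#' @param trajectory_family `"biphasic"` (per-cluster two-phase linear,
#'   default for regional cohorts) or `"logarithmic"`.
#' @param cluster_params Data frame of per-cluster trajectory parameters
#'   (intercept, slope1, psi, slope2); defaults encode breakpoints
#'   6.71 / 7.69 / 10.36 months along the limbic-sensorimotor-association
#'   hierarchy.
#' @param log_params c(beta, intercept) of the global logarithmic curve
#'   `CBF = beta * ln(age) + intercept` (default 16.38, 16.85).
#' @param biphasic_params c(slope1, slope2, psi) of the global biphasic
#'   curve (default 3.52, 0.43, 10.75), anchored to the logarithmic curve's
#'   value at the breakpoint.
#' @param residual_sd_global Between-subject residual SD, ml/100g/min;
#'   applied per (subject, cluster) in regional cohorts and per subject in
#'   global cohorts. The default 6.3 is calibrated by simulation so the
#'   age-CBF correlation of a logarithmic global cohort at n = 119 is
#'   about 0.82.
#' @param residual_sd_voxel Voxel-level i.i.d. residual SD (default 10).
#' @param behavior_effect Partial correlation between the loaded cluster's
#'   age-adjusted mean rCBF and each behavior score (default 0.5).
#' @param behavior_loading Named list mapping behavioral domains to the
#'   cluster each loads on.
#' @param age_range,age_mean,age_sd Truncated-normal age model, months.
#' @param age_distribution `"truncnorm"` (default) or `"uniform"`.
#' @param brain_volume_ml Brain parenchyma volume, mL (constant by design).
#' @param n_pairs Number of ASL control/label pairs (default 10).
#' @param asl_noise_sd Measurement noise added to ASL volumes (default 0,
#'   so quantification round-trips exactly).
#' @param mrd_mean,mrd_sd Cohort distribution of subject MRD, mm (default
#'   0.22 +/- 0.13, truncated below the 0.5 mm exclusion threshold).
#' @param seed Integer seed controlling every random draw.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_subjects = 76,
                             grid_shape = c(20, 24, 20),
                             voxel_size_mm = 2,
                             cluster_fractions = c(limbic = 0.25,
                                                   sensorimotor = 0.35,
                                                   frontoparietal = 0.40),
                             trajectory_family = c("biphasic", "logarithmic"),
                             cluster_params = default_cluster_params(),
                             log_params = c(beta = 16.38, intercept = 16.85),
                             biphasic_params = c(slope1 = 3.52, slope2 = 0.43,
                                                 psi = 10.75),
                             residual_sd_global = 6.3,
                             residual_sd_voxel = 10,
                             behavior_effect = 0.5,
                             behavior_loading = list(
                               motor = "sensorimotor",
                               language = "frontoparietal",
                               cognitive = "limbic"),
                             age_range = c(1.4, 28),
                             age_mean = 12.5, age_sd = 7.1,
                             age_distribution = c("truncnorm", "uniform"),
                             brain_volume_ml = 700,
                             n_pairs = 10,
                             asl_noise_sd = 0,
                             mrd_mean = 0.22, mrd_sd = 0.13,
                             seed = 1) {
  trajectory_family <- match.arg(trajectory_family)
  age_distribution <- match.arg(age_distribution)
  if (n_subjects < 1) stop("configuration error: n_subjects must be positive")
  if (abs(sum(cluster_fractions) - 1) > 1e-8) {
    stop("configuration error: cluster fractions must sum to 1")
  }
  if (!all(cluster_params$cluster %in% names(cluster_fractions))) {
    stop("configuration error: cluster_params/cluster_fractions mismatch")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Evaluate a cluster's mean trajectory
#'
#' Continuous two-phase linear trajectory
#' `intercept + slope1 * min(age, psi) + slope2 * max(age - psi, 0)`.
#'
#' @param params One row of the cluster parameter table.
#' @param age Ages, months.
#' @return Mean rCBF, ml/100g/min.
#' @export
cluster_trajectory <- function(params, age) {
  params$intercept + params$slope1 * pmin(age, params$psi) +
    params$slope2 * pmax(age - params$psi, 0)
}

global_trajectory <- function(config, age) {
  if (config$trajectory_family == "logarithmic") {
    config$log_params[["beta"]] * log(age) + config$log_params[["intercept"]]
  } else {
    bp <- config$biphasic_params
    # anchored so the curve meets the logarithmic fit at the breakpoint
    at_psi <- config$log_params[["beta"]] * log(bp[["psi"]]) +
      config$log_params[["intercept"]]
    b0 <- at_psi - bp[["slope1"]] * bp[["psi"]]
    b0 + bp[["slope1"]] * pmin(age, bp[["psi"]]) +
      bp[["slope2"]] * pmax(age - bp[["psi"]], 0)
  }
}

sample_ages <- function(config, n) {
  lo <- config$age_range[1]; hi <- config$age_range[2]
  if (config$age_distribution == "uniform") {
    return(stats::runif(n, lo, hi))
  }
  plo <- stats::pnorm(lo, config$age_mean, config$age_sd)
  phi <- stats::pnorm(hi, config$age_mean, config$age_sd)
  stats::qnorm(stats::runif(n, plo, phi), config$age_mean, config$age_sd)
}

# ellipsoidal brain mask with a radial three-way partition:
# limbic core, sensorimotor shell, frontoparietal rim
build_mask_and_labels <- function(config) {
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  semi <- d / 2 - 2.5
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  inside <- r2 <= 1
  mask <- array(inside, d)
  idx <- which(inside)
  ord <- order(r2[idx])
  n <- length(idx)
  fr <- config$cluster_fractions[c("limbic", "sensorimotor",
                                   "frontoparietal")]
  n1 <- round(n * fr[1])
  n2 <- round(n * fr[2])
  labels_vec <- integer(n)
  labels_vec[ord[seq_len(n1)]] <- 1L
  labels_vec[ord[n1 + seq_len(n2)]] <- 2L
  labels_vec[ord[(n1 + n2 + 1):n]] <- 3L
  labels <- array(0L, d)
  labels[idx] <- labels_vec
  list(mask = mask, labels = labels, voxel_labels = labels_vec,
       voxel_index = idx)
}

#' Phase-contrast flux table for a target global CBF
#'
#' Inverts the flux-to-CBF relation: the summed four-artery flux equals
#' `target * rho * brain_volume / 100` ml/min, split across the bilateral
#' internal carotid (32% each) and vertebral (18% each) arteries.
#'
#' @param target_global_cbf Target global CBF, ml/100g/min (>= 0).
#' @param brain_volume Brain parenchyma volume, mL.
#' @param rho Tissue density, g/mL.
#' @param split Artery flux proportions (length 4, sums to 1).
#' @return Named numeric vector of per-artery fluxes, ml/min.
#' @export
generate_pc_measurement <- function(target_global_cbf, brain_volume,
                                    rho = 1.06,
                                    split = c(ica_l = 0.32, ica_r = 0.32,
                                              va_l = 0.18, va_r = 0.18)) {
  if (target_global_cbf < 0) stop("target global CBF must be >= 0")
  if (brain_volume <= 0) stop("brain_volume must be positive")
  if (abs(sum(split) - 1) > 1e-10) stop("split must sum to 1")
  total <- target_global_cbf * rho * brain_volume / 100
  total * split
}

#' Motion parameter table with a target MRD
#'
#' Builds a pure-translation random walk whose per-volume step lengths are
#' exponential with the mean chosen so the series MRD equals
#' `target_mrd` in expectation; the first volume is the reference.
#'
#' @param n_volumes Number of volumes.
#' @param target_mrd Target mean relative displacement, mm.
#' @return `n_volumes` x 6 matrix (rotations rad, translations mm).
#' @export
generate_motion_profile <- function(n_volumes, target_mrd) {
  if (n_volumes < 1) stop("n_volumes must be >= 1")
  par <- matrix(0, n_volumes, 6)
  colnames(par) <- c("rot_x", "rot_y", "rot_z",
                     "trans_x", "trans_y", "trans_z")
  if (n_volumes == 1 || target_mrd <= 0) return(par)
  mu <- target_mrd * n_volumes / (n_volumes - 1)
  steps <- stats::rexp(n_volumes - 1, rate = 1 / mu)
  # rescale so the realized MRD equals the target exactly
  steps <- steps * mu * (n_volumes - 1) / sum(steps)
  dirs <- matrix(stats::rnorm(3 * (n_volumes - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  par[-1, 4:6] <- apply(dirs * steps, 2, cumsum)
  par
}

#' ASL control/label series for a known rCBF map
#'
#' Inverts the pCASL kinetic model: the control-minus-label difference that
#' reproduces `truth` under [rcbf_from_asl()] is added to a static baseline
#' (a small fraction of M0, emulating background-suppressed tissue signal).
#' With zero noise the quantification round-trip is exact.
#'
#' @param truth Vector (masked voxels) or 3D array of true rCBF values.
#' @param constants [asl_constants()].
#' @param n_pairs Number of control/label pairs (default 10).
#' @param m0_value Equilibrium magnetization inside the mask.
#' @param base_frac Static tissue signal as a fraction of M0.
#' @param noise_sd Gaussian measurement noise SD per volume.
#' @param motion_profile Optional motion table for the series (2*n_pairs
#'   volumes); generated as all-zero when omitted.
#' @return List with `control`, `label` (voxel x n_pairs matrices),
#'   `m0_pair`, `m0` (averaged), and `motion`.
#' @export
generate_asl_series <- function(truth, constants = asl_constants(),
                                n_pairs = 10, m0_value = 1000,
                                base_frac = 0.02, noise_sd = 0,
                                motion_profile = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  truth <- as.numeric(truth)
  if (any(truth <= 0)) stop("truth map must be positive inside the mask")
  scale <- with(constants,
    6000 * lambda_coeff * exp(pld / t1a) /
      (2 * alpha * t1a * (1 - exp(-label_dur / t1a))))
  m0 <- rep(m0_value, length(truth))
  delta_m <- truth * m0 / scale
  base <- base_frac * m0
  control <- matrix(base + delta_m, length(truth), n_pairs)
  label <- matrix(base, length(truth), n_pairs)
  if (noise_sd > 0) {
    control <- control + stats::rnorm(length(control), 0, noise_sd)
    label <- label + stats::rnorm(length(label), 0, noise_sd)
  }
  m0_pair <- cbind(m0, m0)
  if (noise_sd > 0) m0_pair <- m0_pair + stats::rnorm(length(m0_pair), 0,
                                                      noise_sd)
  if (is.null(motion_profile)) {
    motion_profile <- matrix(0, 2 * n_pairs, 6)
  }
  list(control = control, label = label, m0_pair = m0_pair,
       m0 = rowMeans(m0_pair), motion = motion_profile)
}

#' Behavior scores loaded on regional CBF
#'
#' Draws Bayley-like standard scores (mean 100, SD 15) whose correlation
#' with the loaded cluster's age-adjusted mean rCBF equals
#' `effect`: `score = 100 + 15 (effect * z + sqrt(1 - effect^2) * noise)`,
#' where `z` is the standardized residual of the cluster-mean rCBF after
#' regressing out `log(age)`.
#'
#' @param rcbf Voxel x subject matrix.
#' @param voxel_labels Integer cluster label per voxel (1-based).
#' @param age Subject ages, months.
#' @param cluster_names Names corresponding to labels 1..K.
#' @param loading Named list domain -> cluster name.
#' @param effect Target partial correlation (default 0.5).
#' @return Data frame of per-subject scores, one column per domain.
#' @export
generate_behavior_scores <- function(rcbf, voxel_labels, age,
                                     cluster_names,
                                     loading = list(
                                       motor = "sensorimotor",
                                       language = "frontoparietal",
                                       cognitive = "limbic"),
                                     effect = 0.5) {
  out <- list()
  for (domain in names(loading)) {
    cl <- match(loading[[domain]], cluster_names)
    if (is.na(cl)) stop("unknown cluster name: ", loading[[domain]])
    cm <- colMeans(rcbf[voxel_labels == cl, , drop = FALSE])
    res <- stats::residuals(stats::lm(cm ~ log(age)))
    z <- if (stats::sd(res) > 0) res / stats::sd(res) else res
    noise <- stats::rnorm(length(age))
    out[[domain]] <- 100 + 15 * (effect * z +
                                   sqrt(max(1 - effect^2, 0)) * noise)
  }
  as.data.frame(out)
}

#' Noiseless reference map at a given age
#'
#' Evaluates each cluster's trajectory at `age` over the voxel grid,
#' optionally adding independent noise — an adult-metabolism-like reference
#' pattern for alignment-trajectory analyses.
#'
#' @param cohort A `synthetic_cohort`, or a list with `voxel_labels` and
#'   `cluster_params`.
#' @param age Age (months) at which to evaluate (default 28).
#' @param noise_sd Independent Gaussian noise SD (default 0).
#' @return Numeric vector over masked voxels.
#' @export
generate_reference_map <- function(cohort, age = 28, noise_sd = 0) {
  labs <- cohort$voxel_labels
  cp <- cohort$cluster_params
  vals <- vapply(seq_len(nrow(cp)), function(i)
    cluster_trajectory(cp[i, ], age), numeric(1))
  out <- vals[labs]
  if (noise_sd > 0) out <- out + stats::rnorm(length(out), 0, noise_sd)
  out
}

#' Generate a synthetic regional cohort
#'
#' @param config A [generator_config()].
#' @param include_asl Also generate per-subject ASL control/label series
#'   (memory-heavy; default FALSE).
#' @return A `synthetic_cohort` list: `cohort_table` (age, sex, mrd, ses,
#'   behavior scores, global CBF), `rcbf` (masked-voxel x subject matrix),
#'   `mask`, `labels` (3D), `voxel_labels`, `cluster_names`,
#'   `cluster_params`, `pc_fluxes`, `motion` (per-subject tables),
#'   optionally `asl`, and the `config`.
#' @export
generate_cohort <- function(config = generator_config(),
                            include_asl = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  age <- sample_ages(config, n)
  sex <- stats::rbinom(n, 1, 0.5)
  ses <- round(stats::rnorm(n, 40, 12))
  geo <- build_mask_and_labels(config)
  m <- length(geo$voxel_index)
  cp <- config$cluster_params
  # cluster-mean trajectory per voxel and subject
  traj <- matrix(0, m, n)
  for (i in seq_len(nrow(cp))) {
    vox <- geo$voxel_labels == i
    traj[vox, ] <- matrix(cluster_trajectory(cp[i, ], age), sum(vox), n,
                          byrow = TRUE)
  }
  # between-subject residuals are cluster-specific: each subject deviates
  # from the mean trajectory independently per cluster, so behavior scores
  # loaded on one cluster do not leak into the others
  clus_res <- matrix(stats::rnorm(nrow(cp) * n, 0, config$residual_sd_global),
                     nrow(cp), n)
  vox_res <- matrix(stats::rnorm(m * n, 0, config$residual_sd_voxel), m, n)
  rcbf <- traj + clus_res[geo$voxel_labels, ] + vox_res
  rcbf <- pmax(rcbf, 0.1)   # rCBF is physically positive
  global_cbf <- colMeans(rcbf)
  pc <- t(vapply(global_cbf, generate_pc_measurement,
                 numeric(4), brain_volume = config$brain_volume_ml))
  pc <- as.data.frame(pc)
  pc$brain_volume <- config$brain_volume_ml
  # subject MRD targets ~ gamma(mean, sd), truncated below exclusion
  shape <- (config$mrd_mean / config$mrd_sd)^2
  rate <- shape / config$mrd_mean
  mrd_target <- stats::rgamma(n, shape, rate)
  while (any(mrd_target >= 0.45)) {
    bad <- mrd_target >= 0.45
    mrd_target[bad] <- stats::rgamma(sum(bad), shape, rate)
  }
  motion <- lapply(mrd_target, function(tm)
    generate_motion_profile(2 * config$n_pairs, tm))
  mrd <- vapply(motion, function(p)
    mean_relative_displacement(relative_rms_displacement(p)), numeric(1))
  scores <- generate_behavior_scores(rcbf, geo$voxel_labels, age,
                                     cp$cluster, config$behavior_loading,
                                     config$behavior_effect)
  tab <- data.frame(subject = seq_len(n), age = age, sex = sex,
                    mrd = mrd, ses = ses, global_cbf = global_cbf)
  tab <- cbind(tab, scores)
  out <- list(cohort_table = tab, rcbf = rcbf, mask = geo$mask,
              labels = geo$labels, voxel_labels = geo$voxel_labels,
              voxel_index = geo$voxel_index,
              cluster_names = cp$cluster, cluster_params = cp,
              pc_fluxes = pc, motion = motion, config = config)
  if (include_asl) {
    out$asl <- lapply(seq_len(n), function(j)
      generate_asl_series(rcbf[, j], n_pairs = config$n_pairs,
                          noise_sd = config$asl_noise_sd,
                          motion_profile = motion[[j]]))
  }
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d masked voxels, %d clusters\n",
              ncol(x$rcbf), nrow(x$rcbf), length(x$cluster_names)))
  cat(sprintf("  ages %.1f-%.1f months (mean %.1f), MRD mean %.2f mm\n",
              min(x$cohort_table$age), max(x$cohort_table$age),
              mean(x$cohort_table$age), mean(x$cohort_table$mrd)))
  invisible(x)
}

#' Generate a synthetic global-CBF cohort
#'
#' A lightweight cohort for global-CBF analyses: ages, sex, cohort flag,
#' and global CBF from the configured family (`logarithmic` by default:
#' `CBF = 16.38 ln(age) + 16.85`; or the anchored `biphasic` curve with
#' slopes 3.52 / 0.43 and breakpoint 10.75 months) plus Gaussian residuals.
#'
#' @param n Cohort size (default 119).
#' @param trajectory_family `"logarithmic"` or `"biphasic"`.
#' @param residual_sd Residual SD, ml/100g/min (default 6.3, matching the
#'   calibrated regional default).
#' @param seed Seed.
#' @param config Optional full [generator_config()] overriding the above.
#' @return Data frame with `age`, `sex`, `cohort`, `global_cbf`, and the
#'   noiseless `truth` column.
#' @export
generate_global_cohort <- function(n = 119,
                                   trajectory_family = "logarithmic",
                                   residual_sd = 6.3, seed = 1,
                                   config = NULL) {
  if (is.null(config)) {
    config <- generator_config(n_subjects = n,
                               trajectory_family = trajectory_family,
                               residual_sd_global = residual_sd,
                               seed = seed)
  }
  set.seed(config$seed)
  n <- config$n_subjects
  age <- sample_ages(config, n)
  sex <- stats::rbinom(n, 1, 0.5)
  cohort <- stats::rbinom(n, 1, 0.5)
  truth <- global_trajectory(config, age)
  data.frame(age = age, sex = sex, cohort = cohort,
             global_cbf = truth + stats::rnorm(n, 0, config$residual_sd_global),
             truth = truth)
}

#' Embed masked-voxel values into the 3D grid
#'
#' @param values Vector over masked voxels.
#' @param mask 3D logical mask.
#' @param fill Value outside the mask (default NA).
#' @return 3D array of `dim(mask)`.
#' @export
embed_map <- function(values, mask, fill = NA_real_) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}
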