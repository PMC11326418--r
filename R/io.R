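#' Standard-format input and output
#'
#' NIfTI volumes for maps, masks and label images (via RNifti, preserving
#' voxel size in the image header), TSV tables for cohort covariates,
#' motion parameters and fit summaries, JSON for QC reports, and a YAML
#' pipeline configuration that round-trips losslessly.
#'
#' @name io
NULL

#' Write a 3D map to NIfTI
#'
#' @param values 3D array, or vector over masked voxels with `mask` given.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param mask Optional 3D mask used to embed vector input.
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return The path, invisibly.
#' @rdname io
#' @export
write_map_nifti <- function(values, path, mask = NULL, voxel_size_mm = 2) {
  if (!is.null(mask) && is.null(dim(values))) {
    values <- embed_map(values, as.array(mask) > 0, fill = 0)
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map
#'
#' @param path NIfTI file path.
#' @return List with `values` (array) and `voxel_size_mm`.
#' @rdname io
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = as.array(img),
       voxel_size_mm = RNifti::pixdim(img)[1])
}

#' Write/read a mask as uint8 NIfTI
#'
#' @rdname io
#' @export
write_mask_nifti <- function(mask, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(array(as.integer(as.array(mask) > 0), dim(mask)))
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname io
#' @export
read_mask_nifti <- function(path) {
  as.array(RNifti::readNifti(path)) > 0
}

#' Write/read TSV tables (cohort covariates, motion parameters, summaries)
#'
#' @param x Data frame or matrix.
#' @param col_names Whether the file carries a header row.
#' @rdname io
#' @export
write_tsv <- function(x, path, col_names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col_names)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path, col_names = TRUE) {
  utils::read.table(path, sep = "\t", header = col_names,
                    stringsAsFactors = FALSE)
}

#' Read a 6-column motion parameter file (MCFLIRT order)
#'
#' @rdname io
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion parameter file must have 6 columns")
  colnames(m) <- c("rot_x", "rot_y", "rot_z",
                   "trans_x", "trans_y", "trans_z")
  m
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one serializable object.
#'
#' @param asl [asl_constants()] values.
#' @param motion_threshold_mm Scrubbing/exclusion threshold.
#' @param alpha Voxel-wise family-wise level.
#' @param t_threshold,min_extent Behavior cluster thresholds.
#' @param k_range NMF component range.
#' @param n_perm Permutation count.
#' @param seed Master seed.
#' @param generator [generator_config()] fields (stored as a plain list).
#' @return A `pipeline_config` list.
#' @rdname io
#' @export
pipeline_config <- function(asl = asl_constants(),
                            motion_threshold_mm = 0.5,
                            alpha = 0.05, t_threshold = 2.02,
                            min_extent = 100, k_range = 2:20,
                            n_perm = 10000, seed = 1,
                            generator = list()) {
  structure(list(asl = unclass(asl),
                 motion_threshold_mm = motion_threshold_mm,
                 alpha = alpha, t_threshold = t_threshold,
                 min_extent = min_extent, k_range = as.integer(k_range),
                 n_perm = n_perm, seed = as.integer(seed),
                 generator = generator),
            class = "pipeline_config")
}

#' @rdname io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname io
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$k_range <- as.integer(x$k_range)
  structure(x, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates the stage order: simulate, motion QC, voxel-wise
#' trajectory modelling, fitted map stack, segmented regression on cluster
#' means, opNMF parcellation with K selection, spatial alignment against a
#' reference map, and behavior association. Intended as the programmatic
#' end-to-end driver; the scripts under `analysis/` run the same stages
#' with reporting.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs (NIfTI
#'   maps, TSV tables, config) are written there.
#' @param k_range Component range for K selection (default 2:6 to keep the
#'   programmatic run light; the study range is 2:20).
#' @return List of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         k_range = 2:6) {
  gen_args <- config$generator
  gen_args$seed <- gen_args$seed %||% config$seed
  gcfg <- do.call(generator_config, gen_args)
  cohort <- generate_cohort(gcfg)
  tab <- cohort$cohort_table
  qc <- data.frame(subject = tab$subject, mrd = tab$mrd,
                   excluded = exclude_subject(tab$mrd,
                                              config$motion_threshold_mm))
  keep <- !qc$excluded
  covs <- data.frame(sex = tab$sex, motion = tab$mrd)[keep, ]
  effects <- voxelwise_age_effects(cohort$rcbf[, keep],
                                   tab$age[keep], covs)
  thr <- bonferroni_threshold(config$alpha, nrow(cohort$rcbf))
  stack <- predict_map_stack(effects,
                             covariate_values = list(
                               sex = "average",
                               motion = mean(tab$mrd[keep])))
  seg <- lapply(seq_along(cohort$cluster_names), function(i) {
    cm <- colMeans(cohort$rcbf[cohort$voxel_labels == i, keep, drop = FALSE])
    fit_segmented(tab$age[keep], cm, 1)
  })
  names(seg) <- cohort$cluster_names
  ks <- select_k(cohort$rcbf[, keep], k_range = k_range)
  parc <- opnmf_fit(cohort$rcbf[, keep], ks$k)
  reference <- generate_reference_map(cohort, age = max(tab$age))
  align <- alignment_trajectory(stack, reference)
  set.seed(config$seed)
  beh <- cluster_level_assoc(
    lapply(seq_along(cohort$cluster_names), function(i)
      colMeans(cohort$rcbf[cohort$voxel_labels == i, keep, drop = FALSE])),
    score = tab$motor[keep], age = tab$age[keep], sex = tab$sex[keep],
    motion = tab$mrd[keep], ses = tab$ses[keep])
  result <- list(cohort = cohort, qc = qc, effects = effects,
                 threshold = thr, stack = stack, segmented = seg,
                 k_selection = ks, parcellation = parc,
                 alignment = align, behavior = beh, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    write_tsv(tab, file.path(out_dir, "cohort.tsv"))
    write_tsv(qc, file.path(out_dir, "motion_qc.tsv"))
    write_mask_nifti(cohort$mask, file.path(out_dir, "mask.nii.gz"),
                     gcfg$voxel_size_mm)
    write_map_nifti(effects$z, file.path(out_dir, "age_effect_z.nii.gz"),
                    cohort$mask, gcfg$voxel_size_mm)
    write_map_nifti(array(as.double(cohort$labels), dim(cohort$labels)),
                    file.path(out_dir, "truth_labels.nii.gz"),
                    voxel_size_mm = gcfg$voxel_size_mm)
    write_map_nifti(parc$labels, file.path(out_dir, "nmf_labels.nii.gz"),
                    cohort$mask, gcfg$voxel_size_mm)
    write_tsv(ks$report, file.path(out_dir, "k_selection.tsv"))
    write_tsv(align, file.path(out_dir, "alignment.tsv"))
    write_tsv(beh, file.path(out_dir, "behavior_clusters.tsv"))
  }
  result
}
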