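#' Brain-behavior association with generalized additive models
#'
#' Associations between rCBF and infant developmental functioning are
#' modelled as `rCBF ~ score + s(age) + sex + motion + ses`, with a
#' penalized cubic regression spline (basis dimension 5, smoothing by GCV)
#' absorbing the linear and nonlinear age effect so the behavior term is
#' tested conditional on development.
#'
#' @name behavior_assoc
NULL

#' Fit the behavior GAM for one response
#'
#' @param rcbf Response: rCBF for one voxel or cluster mean, per subject.
#' @param score Behavior score (e.g. a Bayley standard score).
#' @param age Age in months.
#' @param sex 0/1 coded sex.
#' @param motion Head motion covariate (MRD, mm).
#' @param ses Socioeconomic-status covariate.
#' @param spline_k Spline basis dimension (default 5).
#' @return A `gam_fit` list: `t` and `p` of the score term, `beta`,
#'   `edf_age` (effective df of the age smooth), `df_residual`, and the
#'   fitted `mgcv::gam` object.
#' @rdname behavior_assoc
#' @export
fit_gam_behavior <- function(rcbf, score, age, sex = NULL, motion = NULL,
                             ses = NULL, spline_k = 5) {
  n <- length(rcbf)
  if (n < 15) stop("need at least 15 complete subjects")
  df <- data.frame(rcbf = rcbf, score = score, age = age)
  rhs <- sprintf("score + s(age, bs = 'cr', k = %d)", spline_k)
  for (nm in c("sex", "motion", "ses")) {
    v <- get(nm)
    if (!is.null(v)) {
      df[[nm]] <- v
      rhs <- paste(rhs, "+", nm)
    }
  }
  if (anyNA(df)) stop("missing covariates; drop incomplete subjects upstream")
  fit <- mgcv::gam(stats::as.formula(paste("rcbf ~", rhs)), data = df,
                   method = "GCV.Cp")
  sm <- summary(fit)
  pt <- sm$p.table["score", ]
  structure(list(t = pt[["t value"]], p = pt[["Pr(>|t|)"]],
                 beta = pt[["Estimate"]], se = pt[["Std. Error"]],
                 edf_age = unname(sm$edf[1]),
                 df_residual = stats::df.residual(fit), fit = fit),
            class = "gam_fit")
}

#' Voxel-wise behavior t-map
#'
#' @param data Voxel x subject rCBF matrix.
#' @param score,age,sex,motion,ses Per-subject variables as in
#'   [fit_gam_behavior()].
#' @param spline_k Spline basis dimension.
#' @return List with per-voxel `t`, `p`, `beta`, and `flagged` for voxels
#'   whose fit failed.
#' @rdname behavior_assoc
#' @export
voxelwise_behavior_tmap <- function(data, score, age, sex = NULL,
                                    motion = NULL, ses = NULL,
                                    spline_k = 5) {
  data <- as.matrix(data)
  m <- nrow(data)
  t_map <- rep(NA_real_, m)
  p_map <- rep(NA_real_, m)
  beta <- rep(NA_real_, m)
  flagged <- logical(m)
  for (i in seq_len(m)) {
    fit <- tryCatch(
      fit_gam_behavior(data[i, ], score, age, sex, motion, ses, spline_k),
      error = function(e) NULL)
    if (is.null(fit)) {
      flagged[i] <- TRUE
    } else {
      t_map[i] <- fit$t
      p_map[i] <- fit$p
      beta[i] <- fit$beta
    }
  }
  list(t = t_map, p = p_map, beta = beta, flagged = flagged)
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  manh <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = rep(TRUE, 26),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, ])
}

#' Extract suprathreshold voxel clusters
#'
#' Connected components of `{t > t_threshold}` on a 3D grid (positive tail),
#' discarding components smaller than the minimum extent. Volume is
#' `size * voxel_size_mm^3`.
#'
#' @param t_map 3D array of t statistics (NA outside the mask).
#' @param t_threshold Voxel-level threshold (default 2.02).
#' @param min_extent Minimum cluster size in voxels (default 100).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param voxel_size_mm Voxel edge length, mm.
#' @param parcel_labels Optional 3D array of parcel labels; each cluster is
#'   annotated with its dominant parcel.
#' @param two_sided If TRUE, threshold on `|t|`.
#' @return List of clusters, each with `voxels` (index matrix), `size`,
#'   `volume_mm3`, `peak_t`, and `parcel` (if labels given), ordered by
#'   decreasing size.
#' @rdname behavior_assoc
#' @export
extract_clusters <- function(t_map, t_threshold = 2.02, min_extent = 100,
                             connectivity = 26, voxel_size_mm = 2,
                             parcel_labels = NULL, two_sided = FALSE) {
  t_map <- as.array(t_map)
  if (length(dim(t_map)) != 3 || length(t_map) == 0) {
    stop("t_map must be a non-empty 3D array")
  }
  supra <- if (two_sided) abs(t_map) > t_threshold else t_map > t_threshold
  supra[is.na(supra)] <- FALSE
  dims <- dim(t_map)
  offs <- neighbor_offsets(connectivity)
  comp <- array(0L, dims)
  next_id <- 0L
  idx_supra <- which(supra)
  clusters <- list()
  for (start in idx_supra) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    # iterative flood fill from this seed
    queue <- start
    comp[start] <- next_id
    members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      ai <- arrayInd(cur, dims)
      nb <- sweep(offs, 2, as.numeric(ai), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1) * dims[1] +
        (nb[, 3] - 1) * dims[1] * dims[2]
      lin <- lin[supra[lin] & comp[lin] == 0L]
      comp[lin] <- next_id
      queue <- c(queue, lin)
    }
    if (length(members) >= min_extent) {
      cl <- list(voxels = arrayInd(sort(members), dims),
                 size = length(members),
                 volume_mm3 = length(members) * voxel_size_mm^3,
                 peak_t = max(abs(t_map[members])))
      if (!is.null(parcel_labels)) {
        labs <- as.array(parcel_labels)[members]
        tab <- table(labs)
        cl$parcel <- names(tab)[which.max(tab)]
      }
      clusters[[length(clusters) + 1]] <- cl
    }
  }
  clusters[order(-vapply(clusters, `[[`, numeric(1), "size"))]
}

#' Cluster-level behavior association
#'
#' Refits the behavior GAM on cluster-mean rCBF and applies the Bonferroni
#' threshold over the behavioral domains (`0.05 / n_domains`).
#'
#' @param cluster_rcbf Named list (or matrix, clusters x subjects) of
#'   cluster-mean rCBF per subject.
#' @param n_domains Number of behavioral domains tested (default 3).
#' @param alpha Family-wise level (default 0.05).
#' @inheritParams fit_gam_behavior
#' @return Data frame with per-cluster `t`, `p`, `significant`, and the
#'   threshold used.
#' @rdname behavior_assoc
#' @export
cluster_level_assoc <- function(cluster_rcbf, score, age, sex = NULL,
                                motion = NULL, ses = NULL, n_domains = 3,
                                alpha = 0.05, spline_k = 5) {
  if (is.matrix(cluster_rcbf)) {
    cluster_rcbf <- split(cluster_rcbf, row(cluster_rcbf))
  }
  thr <- alpha / n_domains
  rows <- lapply(seq_along(cluster_rcbf), function(i) {
    fit <- fit_gam_behavior(as.numeric(cluster_rcbf[[i]]), score, age,
                            sex, motion, ses, spline_k)
    data.frame(cluster = if (!is.null(names(cluster_rcbf)))
                 names(cluster_rcbf)[i] else as.character(i),
               t = fit$t, p = fit$p, significant = fit$p < thr,
               p_threshold = thr)
  })
  do.call(rbind, rows)
}

#' Domain-by-parcel summary of significant voxels
#'
#' Counts significant voxels per (behavioral domain, parcel) and normalizes
#' each domain's row by its total, as in a river/ribbon plot. Domains with
#' no significant voxels are flagged and left unnormalized.
#'
#' @param domain_clusters Named list (one entry per domain) of cluster lists
#'   from [extract_clusters()] run with `parcel_labels`.
#' @param parcels Character vector of all parcel names (table columns).
#' @return List with `counts` and `proportions` matrices (domain x parcel)
#'   and `empty_domains`.
#' @rdname behavior_assoc
#' @export
behavior_river_summary <- function(domain_clusters, parcels = NULL) {
  domains <- names(domain_clusters)
  if (is.null(parcels)) {
    parcels <- sort(unique(unlist(lapply(domain_clusters, function(cl)
      vapply(cl, function(c) c$parcel %||% NA_character_, character(1))))))
    parcels <- parcels[!is.na(parcels)]
  }
  counts <- matrix(0, length(domains), length(parcels),
                   dimnames = list(domains, parcels))
  for (d in domains) {
    for (cl in domain_clusters[[d]]) {
      if (is.null(cl$parcel)) stop("clusters must carry parcel labels")
      counts[d, cl$parcel] <- counts[d, cl$parcel] + cl$size
    }
  }
  totals <- rowSums(counts)
  props <- counts
  empty <- totals == 0
  props[!empty, ] <- counts[!empty, , drop = FALSE] / totals[!empty]
  list(counts = counts, proportions = props,
       empty_domains = domains[empty])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
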