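#' Spatial map correlation and permutation testing
#'
#' Pearson correlation between two voxel-wise maps over a shared mask, with
#' significance from a free-shuffle permutation null: surrogate maps are
#' built by re-assigning the masked voxel values of the second map, and the
#' empirical p-value is the (add-one smoothed) proportion of null
#' correlations at least as large as the observed one.
#'
#' @name spatial_stats
NULL

masked_values <- function(map, mask = NULL) {
  if (inherits(map, "cbf_map")) {
    if (is.null(mask)) mask <- map$mask
    return(map$values[as.array(mask) > 0])
  }
  map <- as.array(map)
  if (is.null(mask)) as.vector(map) else map[as.array(mask) > 0]
}

#' Pearson correlation of two maps over a mask
#'
#' @param map_a,map_b `cbf_map` objects or numeric arrays of equal shape.
#' @param mask Optional logical/0-1 array selecting voxels.
#' @return Pearson r.
#' @rdname spatial_stats
#' @export
map_correlation <- function(map_a, map_b, mask = NULL) {
  a <- masked_values(map_a, mask)
  b <- masked_values(map_b, mask)
  if (length(a) != length(b)) stop("maps differ in masked voxel count")
  if (length(a) < 3) stop("need at least 3 masked voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant map")
  stats::cor(a, b)
}

#' Permutation p-value for spatial alignment
#'
#' @param n_perm Number of surrogate maps (default 10000).
#' @param seed Seed for the permutation stream.
#' @param tail `"greater"` (default; counts null r >= observed) or
#'   `"two.sided"` (counts |null r| >= |observed|).
#' @inheritParams map_correlation
#' @return List with `r_obs`, `p`, `n_perm`, `null_mean`, `null_sd`, `seed`.
#' @rdname spatial_stats
#' @export
permutation_pvalue <- function(map_a, map_b, mask = NULL, n_perm = 10000,
                               seed = NULL, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1")
  a <- masked_values(map_a, mask)
  b <- masked_values(map_b, mask)
  if (length(a) != length(b)) stop("maps differ in masked voxel count")
  if (length(a) < 3) stop("need at least 3 masked voxels")
  r_obs <- stats::cor(a, b)
  if (!is.null(seed)) set.seed(seed)
  r_null <- vapply(seq_len(n_perm),
                   function(i) stats::cor(a, sample(b)), numeric(1))
  exceed <- if (tail == "greater") sum(r_null >= r_obs)
            else sum(abs(r_null) >= abs(r_obs))
  list(r_obs = r_obs, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
       null_mean = mean(r_null), null_sd = stats::sd(r_null), seed = seed)
}

#' Alignment trajectory across a fitted map stack
#'
#' Correlates each age's fitted rCBF map with a reference map (e.g. an
#' adult cerebral-metabolism pattern), yielding one r per stack age;
#' permutation p-values per age on request.
#'
#' @param stack Voxel x age matrix from [predict_map_stack()] (with an
#'   `ages` attribute), or any voxel x age matrix.
#' @param reference Reference map values over the same voxels.
#' @param ages Optional ages overriding the stack attribute.
#' @param n_perm If > 0, compute a permutation p per age.
#' @param seed Permutation seed.
#' @return Data frame with `age`, `r`, and (optionally) `p_perm`.
#' @rdname spatial_stats
#' @export
alignment_trajectory <- function(stack, reference, ages = NULL,
                                 n_perm = 0, seed = NULL) {
  stack <- as.matrix(stack)
  reference <- as.numeric(reference)
  if (nrow(stack) != length(reference)) stop("grid mismatch")
  if (is.null(ages)) ages <- attr(stack, "ages")
  if (is.null(ages)) ages <- seq_len(ncol(stack))
  r <- apply(stack, 2, stats::cor, y = reference)
  out <- data.frame(age = ages, r = r)
  if (n_perm > 0) {
    out$p_perm <- vapply(seq_len(ncol(stack)), function(j)
      permutation_pvalue(stack[, j], reference, n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + j)$p,
      numeric(1))
  }
  out
}
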