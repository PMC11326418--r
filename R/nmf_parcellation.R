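#' Orthonormal projective NMF parcellation
#'
#' Factorizes a non-negative voxel x subject matrix `X` as `X ~ W H` with
#' `H = W^T X`, `W >= 0` and `W^T W` driven toward the identity, by
#' multiplicative projective updates
#' `W <- W * (X X^T W) / (W W^T X X^T W)` with column renormalization.
#' Orthonormality is a soft property of this scheme: the residual
#' off-diagonal mass of `W^T W` is reported, not enforced exactly. The
#' objective `||X - W W^T X||_F^2` is guarded to be non-increasing by
#' backtracking toward the previous iterate whenever a raw multiplicative
#' step would increase it.
#'
#' @name nmf_parcellation
NULL

pnmf_objective <- function(X, W, x_sq) {
  A <- crossprod(X, W)                       # N x K = X^T W
  x_sq - 2 * sum(A * A) + sum(crossprod(W) * crossprod(A))
}

nndsvd_init <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  M <- nrow(X)
  W <- matrix(0, M, k)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        if (n_up > 0) W[, j] <- sqrt(sv$d[j] * n_up * n_vp) * up / n_up
      } else {
        if (n_un > 0) W[, j] <- sqrt(sv$d[j] * n_un * n_vn) * un / n_un
      }
    }
  }
  # keep strictly positive support so multiplicative updates can move
  W[W < 1e-10] <- 1e-10
  W
}

kmeans_init <- function(X, k, seed) {
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 3, iter.max = 50)
  W <- vapply(seq_len(k), function(j) as.numeric(km$cluster == j),
              numeric(nrow(X)))
  # keep a small positive floor so multiplicative updates can move mass
  # back into a component a voxel did not start in
  pmax(W, 1e-4)
}

opnmf_run <- function(X, W, x_sq, tol, max_iter) {
  W <- sweep(W, 2, pmax(sqrt(colSums(W^2)), 1e-12), "/")
  f <- pnmf_objective(X, W, x_sq)
  trace <- f
  converged <- FALSE
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    A <- crossprod(X, W)                     # N x K
    num <- X %*% A                           # X X^T W
    den <- W %*% crossprod(A)                # W W^T X X^T W
    W_raw <- W * num / pmax(den, 1e-300)
    s <- 1
    repeat {
      W_new <- if (s == 1) W_raw else (1 - s) * W + s * W_raw
      W_new <- sweep(W_new, 2, pmax(sqrt(colSums(W_new^2)), 1e-12), "/")
      f_new <- pnmf_objective(X, W_new, x_sq)
      if (f_new <= f + 1e-12 * max(1, abs(f))) break
      s <- s / 2
      if (s < 1e-6) { W_new <- W; f_new <- f; break }
    }
    rel_change <- (f - f_new) / max(abs(f), 1e-300)
    W <- W_new
    f <- f_new
    trace <- c(trace, f)
    if (rel_change < tol) { converged <- TRUE; break }
  }
  list(W = W, f = f, trace = trace, iterations = iterations,
       converged = converged)
}

#' Fit an orthonormal projective NMF
#'
#' The projective multiplicative update is prone to poor local optima from
#' any single generic initialization, so the default policy (`"auto"`) runs
#' the update from a deterministic NNDSVD start, a kmeans-indicator start,
#' and `n_restarts` seeded random starts, and keeps the solution with the
#' lowest reconstruction error. All starts are deterministic given `seed`.
#'
#' @param X Non-negative voxel x subject matrix.
#' @param k Number of components (clusters).
#' @param init `"auto"` (multi-start, default), `"nndsvd"`, `"kmeans"` or
#'   `"random"`.
#' @param n_restarts Number of additional random starts under `"auto"`.
#' @param seed Seed for kmeans/random initializations.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum multiplicative updates per start.
#' @return A `parcellation` list: `W` (columns unit-norm), `H = W^T X`,
#'   `labels` (hard assignment), `objective` (final `||X - WH||_F^2`),
#'   `objective_trace`, `ortho_residual` (max off-diagonal |W^T W|),
#'   `iterations`, `converged`, and `init` (the winning start).
#' @rdname nmf_parcellation
#' @export
opnmf_fit <- function(X, k, init = c("auto", "nndsvd", "kmeans", "random"),
                      n_restarts = 2, seed = 1, tol = 1e-6,
                      max_iter = 2000) {
  X <- as.matrix(X)
  init <- match.arg(init)
  if (any(X < 0)) stop("X must be non-negative")
  if (all(X == 0)) stop("X must not be all zero")
  if (k < 1 || k > min(dim(X))) stop("k out of range")
  M <- nrow(X)
  random_start <- function(s) {
    set.seed(s)
    matrix(stats::runif(M * k, 0.1, 1), M, k)
  }
  starts <- switch(init,
    nndsvd = list(nndsvd = nndsvd_init(X, k)),
    kmeans = list(kmeans = kmeans_init(X, k, seed)),
    random = list(random = random_start(seed)),
    auto = c(list(nndsvd = nndsvd_init(X, k),
                  kmeans = kmeans_init(X, k, seed)),
             stats::setNames(
               lapply(seq_len(n_restarts), function(i)
                 random_start(seed + i)),
               if (n_restarts > 0) paste0("random", seq_len(n_restarts))
               else character(0)))
  )
  x_sq <- sum(X^2)
  best <- NULL
  best_name <- NULL
  for (nm in names(starts)) {
    run <- opnmf_run(X, starts[[nm]], x_sq, tol, max_iter)
    if (is.null(best) || run$f < best$f) {
      best <- run
      best_name <- nm
    }
  }
  W <- best$W
  H <- crossprod(W, X)
  gram <- crossprod(W)
  structure(list(
    W = W, H = H, labels = hard_assignment(W)$labels,
    objective = best$f, objective_trace = best$trace,
    ortho_residual = max(abs(gram - diag(diag(gram)))),
    iterations = best$iterations, converged = best$converged, k = k,
    init = best_name),
    class = "parcellation")
}

#' Hard cluster assignment from component weights
#'
#' Assigns each voxel to the component with the highest weight in its row of
#' `W`; ties break to the lowest component index. Rows that are entirely
#' zero get label 0 ("unassigned") and are counted.
#'
#' @param W Non-negative voxel x component matrix.
#' @return List with integer `labels` (0 = unassigned) and `n_unassigned`.
#' @rdname nmf_parcellation
#' @export
hard_assignment <- function(W) {
  W <- as.matrix(W)
  labels <- max.col(W, ties.method = "first")
  zero <- rowSums(W != 0) == 0
  labels[zero] <- 0L
  list(labels = as.integer(labels), n_unassigned = sum(zero))
}

cluster_stats <- function(features, labels) {
  features <- as.matrix(features)
  labs <- sort(unique(labels))
  if (length(labs) < 2) stop("need at least 2 non-empty clusters")
  cent <- t(vapply(labs, function(l)
    colMeans(features[labels == l, , drop = FALSE]),
    numeric(ncol(features))))
  list(labs = labs, centroids = cent)
}

#' Davies-Bouldin cluster validity index
#'
#' Mean over clusters of the worst-case ratio
#' `(s_i + s_j) / d(c_i, c_j)`, where `s_i` is the average Euclidean
#' distance of cluster members to their centroid. Lower is better.
#'
#' @param features Observation x feature matrix (here: voxel rows of `X`).
#' @param labels Cluster label per observation.
#' @return The index (scalar).
#' @rdname nmf_parcellation
#' @export
davies_bouldin <- function(features, labels) {
  st <- cluster_stats(features, labels)
  K <- length(st$labs)
  s <- vapply(seq_len(K), function(i) {
    pts <- as.matrix(features)[labels == st$labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, st$centroids[i, ])^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(st$centroids))
  if (any(d[upper.tri(d)] == 0)) stop("coincident cluster centroids")
  ratios <- outer(s, s, "+") / d
  diag(ratios) <- -Inf
  mean(apply(ratios, 1, max))
}

#' Calinski-Harabasz cluster validity index
#'
#' Ratio of between-cluster to within-cluster dispersion scaled by
#' `(N - K) / (K - 1)`. Higher is better.
#'
#' @rdname nmf_parcellation
#' @export
calinski_harabasz <- function(features, labels) {
  features <- as.matrix(features)
  st <- cluster_stats(features, labels)
  K <- length(st$labs)
  N <- nrow(features)
  grand <- colMeans(features)
  n_i <- vapply(st$labs, function(l) sum(labels == l), numeric(1))
  ssb <- sum(n_i * rowSums(sweep(st$centroids, 2, grand)^2))
  ssw <- sum(vapply(seq_len(K), function(i) {
    pts <- features[labels == st$labs[i], , drop = FALSE]
    sum(sweep(pts, 2, st$centroids[i, ])^2)
  }, numeric(1)))
  if (ssw == 0) stop("zero within-cluster dispersion")
  (ssb / (K - 1)) / (ssw / (N - K))
}

#' Select the number of components
#'
#' Runs [opnmf_fit()] for every `k` in `k_range`, computes both validity
#' indices on the voxel subject-profile rows under the hard labels, and
#' selects the `k` with the best summed rank (Davies-Bouldin rank ascending
#' + Calinski-Harabasz rank descending); ties go to the smaller `k`.
#' A `k` whose hard assignment collapses below two non-empty clusters is
#' scored as worst on both indices.
#'
#' @param k_range Integer vector of candidate component counts.
#' @param init Initialization policy per fitted `k`; the sweep defaults to
#'   the economical kmeans-seeded start (the full multi-start policy is
#'   worth its cost only for the final fit at the chosen `k`).
#' @param ... Passed to [opnmf_fit()].
#' @inheritParams opnmf_fit
#' @return A `k_selection` list: `report` data frame (k, db, ch,
#'   reconstruction error), `k` (chosen), and `fits` when `keep_fits`.
#' @param keep_fits Keep every fitted parcellation (memory-heavy).
#' @rdname nmf_parcellation
#' @export
select_k <- function(X, k_range = 2:20, keep_fits = FALSE,
                     init = "kmeans", ...) {
  if (length(k_range) == 0) stop("empty k_range")
  X <- as.matrix(X)
  rows <- vector("list", length(k_range))
  fits <- if (keep_fits) vector("list", length(k_range)) else NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- opnmf_fit(X, k, init = init, ...)
    db <- tryCatch(davies_bouldin(X, fit$labels), error = function(e) Inf)
    ch <- tryCatch(calinski_harabasz(X, fit$labels), error = function(e) -Inf)
    rows[[i]] <- data.frame(k = k, db = db, ch = ch,
                            reconstruction_error = fit$objective,
                            n_clusters = length(unique(fit$labels)))
    if (keep_fits) fits[[i]] <- fit
  }
  report <- do.call(rbind, rows)
  score <- rank(report$db, ties.method = "min") +
    rank(-report$ch, ties.method = "min")
  chosen <- report$k[which.min(score)]   # which.min takes the first = smallest k
  structure(list(report = report, k = chosen, rank_score = score,
                 fits = fits),
            class = "k_selection")
}
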