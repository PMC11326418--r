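#' Segmented (breakpoint) regression of CBF against age
#'
#' Continuous piecewise-linear models with 0 or more breakpoints, fitted by
#' iterative linearization: at the current breakpoint estimates `psi` the
#' model is linearized as a regression on `x`, the hinge terms
#' `(x - psi_j)_+`, and the indicator correction terms `-(x > psi_j)`; the
#' coefficient ratio of each correction to its hinge term gives the
#' breakpoint update, iterated until the step is below tolerance.
#' Breakpoint standard errors come from the delta method
#' (`SE(psi) = SE(gamma)/|beta_U|`). If the iteration fails to converge the
#' fit falls back to a profile grid search over candidate breakpoints with a
#' warning.
#'
#' @name segmented_regression
NULL

seg_design <- function(x, psi, with_v = TRUE) {
  X <- cbind(`(Intercept)` = 1, x = x)
  for (j in seq_along(psi)) {
    X <- cbind(X, pmax(x - psi[j], 0))
    colnames(X)[ncol(X)] <- paste0("U", j)
  }
  if (with_v) {
    for (j in seq_along(psi)) {
      X <- cbind(X, -as.numeric(x > psi[j]))
      colnames(X)[ncol(X)] <- paste0("V", j)
    }
  }
  X
}

check_phases <- function(x, psi, min_per_phase = 3) {
  bounds <- c(-Inf, sort(psi), Inf)
  counts <- table(cut(x, bounds))
  if (any(counts < min_per_phase)) {
    stop(sprintf("degenerate fit: a phase contains fewer than %d points",
                 min_per_phase))
  }
  invisible(counts)
}

seg_rss <- function(x, y, psi) {
  X <- seg_design(x, psi, with_v = FALSE)
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# profile grid search over breakpoint locations (fallback / oracle route)
seg_grid_search <- function(x, y, n_breakpoints, step = 0.05) {
  rng <- range(x)
  grid <- seq(rng[1] + step, rng[2] - step, by = step)
  grid <- grid[vapply(grid, function(p)
    sum(x <= p) >= 3 && sum(x > p) >= 3, logical(1))]
  if (length(grid) == 0) {
    stop("breakpoint cannot be placed with at least 3 points per phase")
  }
  if (n_breakpoints == 1) {
    rss <- vapply(grid, function(p) seg_rss(x, y, p), numeric(1))
    return(grid[which.min(rss)])
  }
  # sequential conditional search for >1 breakpoint: coarse but robust
  psi <- stats::quantile(x, seq_len(n_breakpoints) / (n_breakpoints + 1),
                         names = FALSE)
  for (sweep in 1:5) {
    for (j in seq_len(n_breakpoints)) {
      cand <- grid
      rss <- vapply(cand, function(p) {
        trial <- sort(replace(psi, j, p))
        if (any(diff(trial) < step)) return(Inf)
        ok <- tryCatch({check_phases(x, trial); TRUE},
                       error = function(e) FALSE)
        if (!ok) return(Inf)
        seg_rss(x, y, trial)
      }, numeric(1))
      psi[j] <- cand[which.min(rss)]
      psi <- sort(psi)
    }
  }
  psi
}

# invert the extra-sum-of-squares F test over the profile RSS; more
# faithful coverage than the first-order delta interval, which ignores the
# curvature of the profile around the optimum
profile_ci_1bp <- function(x, y, rss_hat, n, level = 0.95) {
  df <- n - 4
  thr <- rss_hat * (1 + stats::qf(level, 1, df) / df)
  grid <- seq(min(x) + 0.02, max(x) - 0.02, length.out = 400)
  grid <- grid[vapply(grid, function(p)
    sum(x <= p) >= 3 && sum(x > p) >= 3, logical(1))]
  rss <- vapply(grid, function(p) seg_rss(x, y, p), numeric(1))
  inside <- grid[rss <= thr]
  if (length(inside) == 0) return(c(NA_real_, NA_real_))
  range(inside)
}

seg_finalize <- function(x, y, psi, n, converged, method, ci = "profile") {
  check_phases(x, psi)
  k <- length(psi)
  X <- seg_design(x, psi, with_v = FALSE)
  fit <- stats::lm(y ~ X - 1)
  rss <- sum(stats::residuals(fit)^2)
  p_eff <- 2 + 2 * k          # intercept, slope, and (hinge, psi) per break
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  # per-phase slopes: cumulative sums of x and hinge coefficients
  idx <- 2:(2 + k)            # positions of x, U1..Uk in cf
  slopes <- cumsum(cf[idx])
  slope_se <- vapply(seq_len(k + 1), function(j) {
    sel <- idx[seq_len(j)]
    sqrt(sum(vc[sel, sel]))
  }, numeric(1))
  # delta-method psi SEs from the V-augmented design at the solution
  Xv <- seg_design(x, psi, with_v = TRUE)
  fv <- tryCatch(stats::lm(y ~ Xv - 1), error = function(e) NULL)
  psi_se <- rep(NA_real_, k)
  if (!is.null(fv) && fv$rank == ncol(Xv)) {
    smv <- suppressWarnings(summary(fv))$coefficients
    for (j in seq_len(k)) {
      bu <- smv[paste0("XvU", j), "Estimate"]
      sg <- smv[paste0("XvV", j), "Std. Error"]
      if (is.finite(bu) && abs(bu) > 0) psi_se[j] <- sg / abs(bu)
    }
  }
  tss <- sum((y - mean(y))^2)
  adj_r2 <- 1 - (rss / (n - p_eff)) / (tss / (n - 1))
  psi_ci <- cbind(low = psi - stats::qt(0.975, n - p_eff) * psi_se,
                  high = psi + stats::qt(0.975, n - p_eff) * psi_se)
  if (identical(ci, "profile") && k == 1) {
    pci <- profile_ci_1bp(x, y, rss, n)
    if (all(is.finite(pci))) psi_ci <- cbind(low = pci[1], high = pci[2])
  }
  if (identical(ci, "none")) psi_ci <- psi_ci * NA_real_
  structure(list(
    n_breakpoints = k, psi = unname(psi), psi_se = psi_se,
    psi_ci = psi_ci,
    slopes = unname(slopes), slope_se = slope_se,
    intercept = unname(cf[1]), rss = rss, n = n, n_params = p_eff,
    df_residual = n - p_eff, adj_r2 = adj_r2,
    sigma = sqrt(rss / (n - p_eff)),
    converged = converged, method = method,
    fitted = unname(stats::fitted(fit)), x = x, y = y),
    class = "segmented_fit")
}

#' Fit a segmented regression
#'
#' @param age Predictor (months); must span each breakpoint with at least 3
#'   points per phase.
#' @param y Response (CBF, ml/100g/min).
#' @param n_breakpoints Number of breakpoints (0-3).
#' @param init_psi Optional starting breakpoint value(s); defaults to
#'   interior quantiles, with multi-start from the quartiles on failure.
#' @param covariates Optional data frame; when supplied, `y` is residualized
#'   on the covariates (retaining its mean) before segmented fitting.
#' @param tol Convergence tolerance on the breakpoint step, in age units.
#' @param max_iter Maximum linearization iterations.
#' @param ci Breakpoint interval construction: `"profile"` (default for one
#'   breakpoint; inverts the profile-RSS F test), `"delta"` (first-order
#'   delta method with t quantiles; always used for 2+ breakpoints), or
#'   `"none"`.
#' @return A `segmented_fit`: breakpoints `psi` with SE and 95% CI,
#'   per-phase `slopes` with SE, `rss`, `adj_r2`, and fit metadata.
#' @rdname segmented_regression
#' @export
fit_segmented <- function(age, y, n_breakpoints = 1, init_psi = NULL,
                          covariates = NULL, tol = 1e-8, max_iter = 100,
                          ci = c("profile", "delta", "none")) {
  ci <- match.arg(ci)
  x <- as.numeric(age)
  y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  n <- length(y)
  k <- n_breakpoints
  if (k < 0 || k > 3) stop("n_breakpoints must be between 0 and 3")
  # every phase needs at least 3 points for identifiable slopes
  if (n < 3 * (k + 1)) stop("too few observations for this many phases")
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    y <- stats::residuals(stats::lm(y ~ ., data = cv)) + mean(y)
  }
  if (k == 0) {
    fit <- stats::lm(y ~ x)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((y - mean(y))^2)
    sm <- suppressWarnings(summary(fit))
    return(structure(list(
      n_breakpoints = 0L, psi = numeric(0), psi_se = numeric(0),
      psi_ci = matrix(numeric(0), 0, 2),
      slopes = unname(stats::coef(fit)[2]),
      slope_se = sm$coefficients[2, 2],
      intercept = unname(stats::coef(fit)[1]), rss = rss, n = n,
      n_params = 2L, df_residual = n - 2L,
      adj_r2 = sm$adj.r.squared, sigma = sm$sigma,
      converged = TRUE, method = "ols",
      fitted = unname(stats::fitted(fit)), x = x, y = y),
      class = "segmented_fit"))
  }
  rng <- range(x)
  starts <- list()
  if (!is.null(init_psi)) starts <- c(starts, list(sort(init_psi)))
  if (k == 1) {
    # screen the profile RSS at every admissible inter-observation midpoint
    # to locate the global basin; the iteration then refines within it
    xs <- sort(unique(x))
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    mids <- mids[vapply(mids, function(p)
      sum(x <= p) >= 3 && sum(x > p) >= 3, logical(1))]
    if (length(mids) > 0) {
      rss_mid <- vapply(mids, function(p) seg_rss(x, y, p), numeric(1))
      starts <- c(starts, list(mids[which.min(rss_mid)]))
    }
  }
  starts <- c(starts,
              list(stats::quantile(x, seq_len(k) / (k + 1), names = FALSE)))
  if (k == 1) {
    starts <- c(starts, list(stats::quantile(x, 0.25, names = FALSE),
                             stats::quantile(x, 0.75, names = FALSE)))
  }
  run_muggeo <- function(psi) {
    rss <- seg_rss(x, y, psi)
    for (iter in seq_len(max_iter)) {
      X <- seg_design(x, psi, with_v = TRUE)
      fit <- stats::lm.fit(X, y)
      if (fit$rank < ncol(X)) return(NULL)
      cf <- fit$coefficients
      bu <- cf[paste0("U", seq_len(k))]
      gm <- cf[paste0("V", seq_len(k))]
      if (any(!is.finite(bu)) || any(abs(bu) < 1e-12)) return(NULL)
      step <- gm / bu
      # accept only RSS-non-increasing, in-range, order-preserving steps:
      # halving the step length makes the iteration monotone in the profile
      # RSS and so free of the oscillation the raw update can fall into
      h <- 1
      accepted <- FALSE
      while (h >= 1e-8) {
        psi_new <- sort(psi + h * step)
        ok <- all(psi_new > rng[1] & psi_new < rng[2]) &&
          (k == 1 || min(diff(psi_new)) > 1e-8)
        if (ok) {
          rss_new <- seg_rss(x, y, psi_new)
          if (rss_new <= rss + 1e-12 * max(1, rss)) {
            accepted <- TRUE
            break
          }
        }
        h <- h / 2
      }
      if (!accepted) break   # local minimum of the profile RSS
      moved <- max(abs(psi_new - psi))
      psi <- psi_new
      rss <- rss_new
      if (moved < tol) break
    }
    ok <- tryCatch({check_phases(x, psi); TRUE}, error = function(e) FALSE)
    if (!ok) return(NULL)
    psi
  }
  for (s in starts) {
    psi <- tryCatch(run_muggeo(s), error = function(e) NULL)
    if (!is.null(psi)) {
      return(seg_finalize(x, y, psi, n, converged = TRUE,
                          method = "iterative", ci = ci))
    }
  }
  warning("breakpoint iteration did not converge; using profile grid search")
  psi <- seg_grid_search(x, y, k)
  seg_finalize(x, y, psi, n, converged = FALSE, method = "grid", ci = ci)
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented fit: %d breakpoint(s), n = %d [%s]\n",
              x$n_breakpoints, x$n, x$method))
  if (x$n_breakpoints > 0) {
    for (j in seq_len(x$n_breakpoints)) {
      cat(sprintf("  psi%d = %.3f (SE %.3f, 95%% CI %.2f-%.2f)\n", j,
                  x$psi[j], x$psi_se[j], x$psi_ci[j, 1], x$psi_ci[j, 2]))
    }
  }
  cat("  slopes:", paste(sprintf("%.3f", x$slopes), collapse = ", "), "\n")
  cat(sprintf("  RSS %.3f, adj R2 %.4f\n", x$rss, x$adj_r2))
  invisible(x)
}

#' Compare nested segmented fits by extra-sum-of-squares F test
#'
#' @param fit_simple,fit_complex `segmented_fit` objects on the same data,
#'   with `fit_complex` having more breakpoints.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @rdname segmented_regression
#' @export
compare_segmented <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "segmented_fit"),
            inherits(fit_complex, "segmented_fit"))
  if (fit_simple$n != fit_complex$n ||
      !isTRUE(all.equal(fit_simple$x, fit_complex$x))) {
    stop("fits are not on identical data")
  }
  if (fit_complex$n_params <= fit_simple$n_params) {
    stop("fit_complex must have more parameters than fit_simple")
  }
  df1 <- fit_complex$n_params - fit_simple$n_params
  df2 <- fit_complex$df_residual
  dss <- max(fit_simple$rss - fit_complex$rss, 0)
  F <- (dss / df1) / (fit_complex$rss / df2)
  if (fit_complex$rss == 0) F <- if (dss == 0) 0 else Inf
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Choose the number of breakpoints
#'
#' Starts from the straight-line model and adds breakpoints while the
#' extra-sum-of-squares F test is significant at `alpha` and the adjusted
#' R-squared increases; returns the last accepted fit.
#'
#' @param max_breakpoints Largest breakpoint count to consider (default 3).
#' @param alpha Significance level for each incremental F test.
#' @inheritParams fit_segmented
#' @return The selected `segmented_fit`, with the comparison table in
#'   `attr(, "comparisons")`.
#' @rdname segmented_regression
#' @export
select_n_breakpoints <- function(age, y, max_breakpoints = 3, alpha = 0.05,
                                 covariates = NULL) {
  current <- fit_segmented(age, y, 0, covariates = covariates)
  comparisons <- list()
  for (k in seq_len(max_breakpoints)) {
    candidate <- tryCatch(
      fit_segmented(age, y, k, covariates = covariates),
      error = function(e) NULL, warning = function(w)
        suppressWarnings(fit_segmented(age, y, k, covariates = covariates)))
    if (is.null(candidate)) break
    cmp <- compare_segmented(current, candidate)
    comparisons[[k]] <- c(n_breakpoints = k, cmp)
    if (cmp$p < alpha && candidate$adj_r2 > current$adj_r2) {
      current <- candidate
    } else {
      break
    }
  }
  attr(current, "comparisons") <- comparisons
  current
}

#' Voxel-wise breakpoint maps
#'
#' Fits a one-breakpoint segmented regression to every voxel's rCBF
#' trajectory and collects the estimated breakpoint ages, with per-cluster
#' histograms when labels are supplied. Non-converging voxels are flagged
#' and excluded from the histograms.
#'
#' @param data Voxel x subject rCBF matrix.
#' @param age Subject ages, months.
#' @param labels Optional integer/character cluster label per voxel.
#' @param covariates Optional covariates residualized out per voxel.
#' @return List with `psi` (per-voxel breakpoint, NA where flagged),
#'   `flagged`, `n_failed`, and `by_cluster` (list of breakpoint vectors).
#' @rdname segmented_regression
#' @export
voxelwise_breakpoints <- function(data, age, labels = NULL,
                                  covariates = NULL) {
  data <- as.matrix(data)
  m <- nrow(data)
  psi <- rep(NA_real_, m)
  flagged <- logical(m)
  for (i in seq_len(m)) {
    fit <- tryCatch(
      suppressWarnings(fit_segmented(age, data[i, ], 1,
                                     covariates = covariates, ci = "none")),
      error = function(e) NULL)
    if (is.null(fit)) flagged[i] <- TRUE else psi[i] <- fit$psi
  }
  by_cluster <- NULL
  if (!is.null(labels)) {
    keep <- !flagged
    by_cluster <- split(psi[keep], labels[keep])
  }
  list(psi = psi, flagged = flagged, n_failed = sum(flagged),
       by_cluster = by_cluster)
}
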