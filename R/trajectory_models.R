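#' Akaike weights from AIC values
#'
#' Computes relative AIC differences `dAIC_i = AIC_i - min(AIC)`, model
#' likelihoods `exp(-dAIC_i/2)`, and normalized Akaike weights, which can be
#' read as the probability that each model is the best of the candidate set.
#'
#' @param aic Numeric vector of AIC values.
#' @return Numeric vector of weights in (0, 1] summing to 1.
#' @export
akaike_weights <- function(aic) {
  if (length(aic) == 0) stop("need at least one AIC value")
  if (any(is.na(aic))) stop("AIC values must not be missing")
  # -Inf arises from perfect (zero-residual) fits: all weight goes there
  if (min(aic) == -Inf) {
    return(as.numeric(aic == -Inf) / sum(aic == -Inf))
  }
  lik <- exp(-(aic - min(aic)) / 2)
  lik / sum(lik)
}

model_families <- c("linear", "logarithmic", "exponential", "poisson",
                    "quadratic")

fit_one_family <- function(family, age, y, covariates = NULL) {
  df <- data.frame(age = age, y = y)
  cov_terms <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    cov_terms <- names(covariates)
  }
  rhs <- function(base) paste(c(base, cov_terms), collapse = " + ")
  fit <- switch(family,
    linear = stats::lm(stats::as.formula(paste("y ~", rhs("age"))), data = df),
    logarithmic = {
      if (any(age <= 0)) stop("logarithmic family requires positive ages")
      stats::lm(stats::as.formula(paste("y ~", rhs("log(age)"))), data = df)
    },
    quadratic = stats::lm(stats::as.formula(
      paste("y ~", rhs(c("age", "I(age^2)")))), data = df),
    exponential = {
      # y = a * exp(b * age) (+ linear covariates), log-linear start values
      eps <- max(1e-6, 1e-6 * max(abs(y)))
      lf <- stats::lm(log(pmax(y, eps)) ~ age, data = df)
      start <- list(a = exp(stats::coef(lf)[[1]]), b = stats::coef(lf)[[2]])
      form <- paste("y ~ a * exp(b * age)",
                    if (length(cov_terms))
                      paste("+", paste(sprintf("c_%s * %s", cov_terms,
                                               cov_terms), collapse = " + "))
                    else "")
      if (length(cov_terms)) {
        for (ct in cov_terms) start[[paste0("c_", ct)]] <- 0
      }
      minpack.lm::nlsLM(stats::as.formula(form), data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    poisson = {
      # continuous CBF rounded to integers so the Poisson log-likelihood is
      # defined; a documented approximation isolated to this family
      dfp <- df
      dfp$y <- round(pmax(df$y, 0))
      stats::glm(stats::as.formula(paste("y ~", rhs("age"))),
                 family = stats::poisson(), data = dfp)
    },
    stop("unknown model family: ", family)
  )
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- length(y)
  list(family = family, fit = fit, logLik = as.numeric(ll), k = k,
       aic = -2 * as.numeric(ll) + 2 * k,
       bic = -2 * as.numeric(ll) + log(n) * k,
       r = stats::cor(stats::fitted(fit), y))
}

#' Fit the five candidate developmental models
#'
#' Fits linear, logarithmic, exponential, Poisson (log-link GLM) and
#' quadratic-polynomial models of CBF against age, each with optional linear
#' covariates, and ranks them by AIC via Akaike weights. The exponential
#' family `y = a e^{b age}` is fitted by nonlinear least squares with a
#' log-linear start; the Poisson family rounds the response so its
#' log-likelihood is defined.
#'
#' @param age Ages in months (positive).
#' @param y Response (global or regional CBF, ml/100g/min).
#' @param covariates Optional data frame of linear covariates (e.g. sex,
#'   head motion, cohort).
#' @param families Character vector of families to fit.
#' @return A `model_fit_set`: data frame with per-model log-likelihood,
#'   parameter count, AIC, BIC, dAIC and Akaike weight, plus the fitted
#'   objects in `attr(, "fits")`.
#' @export
fit_candidate_models <- function(age, y, covariates = NULL,
                                 families = model_families) {
  stopifnot(length(age) == length(y), length(families) >= 1)
  fits <- lapply(families, fit_one_family, age = age, y = y,
                 covariates = covariates)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  w <- akaike_weights(aic)
  out <- data.frame(
    family = families,
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aic = aic,
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    d_aic = aic - min(aic),
    w_aic = w,
    r = vapply(fits, `[[`, numeric(1), "r"),
    stringsAsFactors = FALSE
  )
  attr(out, "fits") <- fits
  class(out) <- c("model_fit_set", class(out))
  out
}

#' Covariate-adjusted logarithmic age model
#'
#' Ordinary least squares of `y ~ log(age) + covariates` (natural log).
#' Returns the age coefficient, the goodness-of-fit correlation `r` between
#' fitted and observed values, the two-tailed p-value of the age term, and
#' the signed probit statistic `Z = sign(beta) * qnorm(1 - p/2)`.
#'
#' @inheritParams fit_candidate_models
#' @return List with `coefficients`, `beta_age`, `intercept`, `se_age`,
#'   `t_age`, `p_age`, `z`, `r`, `sigma`, `df_residual`, and the `lm` fit.
#' @export
fit_log_model <- function(age, y, covariates = NULL) {
  if (any(age <= 0)) stop("ages must be positive for the logarithmic model")
  df <- data.frame(log_age = log(age), y = y)
  rhs <- "log_age"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    rhs <- paste(c("log_age", names(covariates)), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
  if (fit$rank < length(stats::coef(fit))) stop("collinear design")
  sm <- suppressWarnings(summary(fit))   # zero-noise recovery is a valid use
  ct <- sm$coefficients["log_age", ]
  p <- ct[["Pr(>|t|)"]]
  z <- sign(ct[["Estimate"]]) *
    stats::qnorm(max(p, 1e-300) / 2, lower.tail = FALSE)
  list(coefficients = stats::coef(fit),
       beta_age = ct[["Estimate"]], intercept = stats::coef(fit)[["(Intercept)"]],
       se_age = ct[["Std. Error"]], t_age = ct[["t value"]], p_age = p,
       z = z, r = stats::cor(stats::fitted(fit), y), sigma = sm$sigma,
       df_residual = fit$df.residual, fit = fit)
}

#' Voxel-wise logarithmic age-effect maps
#'
#' Fits `rCBF ~ log(age) + covariates` at every masked voxel by a single QR
#' decomposition of the shared design matrix, and returns per-voxel beta,
#' goodness-of-fit r, and the signed probit Z statistic of the age term.
#' Voxels with (numerically) zero residual variance and zero age effect are
#' flagged and assigned Z = 0.
#'
#' @param data Voxel x subject matrix of rCBF values.
#' @param age Subject ages in months.
#' @param covariates Optional data frame of per-subject covariates.
#' @return An `effect_map` list: `beta`, `se`, `t`, `p`, `z`, `r`,
#'   `flagged` (logical), `coefficients` (voxel x term matrix), and design
#'   metadata used by [predict_map_stack()].
#' @export
voxelwise_age_effects <- function(data, age, covariates = NULL) {
  data <- as.matrix(data)
  n <- ncol(data)
  if (length(age) != n) stop("column count must equal subject count")
  if (any(age <= 0)) stop("ages must be positive")
  X <- cbind(`(Intercept)` = 1, log_age = log(age))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    X <- cbind(X, as.matrix(covariates))
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("collinear design")
  # coefficients for all voxels at once: B is p x M
  B <- qr.coef(qrX, t(data))
  fitted <- X %*% B
  res <- t(data) - fitted
  df_res <- n - p
  rss <- colSums(res^2)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qrX))
  se_beta <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- B[2, ]
  tt <- beta / se_beta
  pval <- 2 * stats::pt(abs(tt), df_res, lower.tail = FALSE)
  tss <- rowSums((data - rowMeans(data))^2)
  flagged <- !is.finite(tt) | tss == 0
  tt[flagged] <- 0
  pval[flagged] <- 1
  z <- sign(beta) * stats::qnorm(pmax(pval, 1e-300) / 2, lower.tail = FALSE)
  z[flagged] <- 0
  r <- suppressWarnings(sqrt(pmax(1 - rss / tss, 0)))
  r[!is.finite(r)] <- 0
  structure(list(beta = beta, se = se_beta, t = tt, p = pval, z = z, r = r,
                 flagged = flagged, coefficients = t(B),
                 terms = colnames(X), df_residual = df_res),
            class = "effect_map")
}

#' Bonferroni voxel-wise thresholds
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (e.g. gray-matter voxels).
#' @return List with the per-test `p_threshold = alpha/n_tests` and the
#'   two-tailed `z_threshold = qnorm(1 - p_threshold/2)`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("invalid alpha")
  if (n_tests < 1) stop("n_tests must be >= 1")
  p <- alpha / n_tests
  list(p_threshold = p,
       z_threshold = stats::qnorm(p / 2, lower.tail = FALSE))
}

#' Fitted rCBF maps across infancy
#'
#' Predicts each voxel's rCBF from the fitted logarithmic model at a grid of
#' ages (default 1 to 28 months in steps of 0.5, i.e. 55 maps), fixing head
#' motion at the cohort-average MRD and averaging the sex effect over both
#' levels.
#'
#' @param fits An `effect_map` from [voxelwise_age_effects()].
#' @param ages Ages (months) at which to predict.
#' @param covariate_values Named list giving the value at which each
#'   covariate term is fixed; entries named `"average"` use 0.5 (the mean of
#'   a 0/1 coded covariate). Default: `list(sex = "average", motion = 0.22)`.
#' @return Matrix of predictions, voxels x ages, with `ages` attribute.
#' @export
predict_map_stack <- function(fits, ages = seq(1, 28, by = 0.5),
                              covariate_values = list(sex = "average",
                                                      motion = 0.22)) {
  stopifnot(inherits(fits, "effect_map"))
  if (any(ages <= 0)) stop("requested ages must be positive")
  terms <- fits$terms
  newx <- matrix(0, nrow = length(ages), ncol = length(terms),
                 dimnames = list(NULL, terms))
  newx[, "(Intercept)"] <- 1
  newx[, "log_age"] <- log(ages)
  for (term in setdiff(terms, c("(Intercept)", "log_age"))) {
    val <- covariate_values[[term]]
    if (is.null(val)) stop("no value supplied for covariate term: ", term)
    newx[, term] <- if (identical(val, "average")) 0.5 else as.numeric(val)
  }
  pred <- fits$coefficients %*% t(newx)
  attr(pred, "ages") <- ages
  pred
}

#' rCBF growth-rate maps
#'
#' The first derivative of the fitted logarithmic curves: for
#' `rCBF = beta * ln(age) + ...`, the rate at a given age is `beta / age`
#' in ml/100g/min per month.
#'
#' @param fits An `effect_map`, or a numeric vector of per-voxel logarithmic
#'   age coefficients.
#' @param ages Ages (months) at which to evaluate the rate.
#' @return Matrix of rates, voxels x ages, with `ages` attribute.
#' @export
rate_maps <- function(fits, ages = seq(1, 28, by = 0.5)) {
  if (any(ages <= 0)) stop("ages must be positive")
  beta <- if (inherits(fits, "effect_map")) fits$beta else as.numeric(fits)
  out <- outer(beta, ages, function(b, a) b / a)
  attr(out, "ages") <- ages
  out
}
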