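test_that("Akaike weights normalize relative model likelihoods", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  # dAIC (0, 2, 4): normalized e^{0}, e^{-1}, e^{-2}
  lik <- exp(-c(0, 2, 4) / 2)
  expect_equal(akaike_weights(c(10, 12, 14)), lik / sum(lik),
               tolerance = 1e-12)
  expect_equal(akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(akaike_weights(7), 1)
  expect_equal(sum(akaike_weights(rnorm(10, 100, 5))), 1, tolerance = 1e-12)
  # invariant under adding a constant
  a <- c(101, 99, 104)
  expect_equal(akaike_weights(a), akaike_weights(a + 50), tolerance = 1e-12)
  expect_error(akaike_weights(numeric(0)), "at least one")
})

test_that("the five candidate families are fitted with the exact AIC identity", {
  set.seed(21)
  d <- generate_global_cohort(119, "logarithmic", seed = 21)
  fits <- fit_candidate_models(d$age, d$global_cbf)
  expect_setequal(fits$family, c("linear", "logarithmic", "exponential",
                                 "poisson", "quadratic"))
  expect_equal(fits$aic, -2 * fits$logLik + 2 * fits$k, tolerance = 1e-12)
  expect_equal(fits$bic, -2 * fits$logLik + log(119) * fits$k,
               tolerance = 1e-12)
  expect_equal(sum(fits$w_aic), 1, tolerance = 1e-12)
  expect_equal(min(fits$d_aic), 0)
  # data generated from the logarithmic curve: it wins the comparison
  expect_equal(fits$family[which.max(fits$w_aic)], "logarithmic")
  expect_error(fit_candidate_models(c(-1, 1, 2, 3, 4, 5, 6, 7), rnorm(8),
                                    families = "logarithmic"), "positive")
})

test_that("each ordinary family recovers its own zero-noise coefficients", {
  age <- seq(1.4, 28, length.out = 60)
  cases <- list(
    linear = list(y = 2 + 1.5 * age, coef = c(2, 1.5)),
    logarithmic = list(y = 16.85 + 16.38 * log(age), coef = c(16.85, 16.38)),
    quadratic = list(y = 5 + 2 * age - 0.03 * age^2, coef = c(5, 2, -0.03)),
    exponential = list(y = 20 * exp(0.05 * age), coef = c(20, 0.05))
  )
  for (fam in names(cases)) {
    fit <- fit_candidate_models(age, cases[[fam]]$y, families = fam)
    got <- unname(coef(attr(fit, "fits")[[1]]$fit))
    expect_equal(got, cases[[fam]]$coef, tolerance = 1e-6)
  }
  # Poisson family against GLM-generated integer data
  set.seed(2)
  mu <- exp(3 + 0.05 * age)
  y <- rpois(60, mu)
  fit <- fit_candidate_models(age, y, families = "poisson")
  expect_equal(unname(coef(attr(fit, "fits")[[1]]$fit)), c(3, 0.05),
               tolerance = 0.05)
})

test_that("the logarithmic model recovers the global curve and its Z pairing", {
  age <- seq(1.4, 28, length.out = 119)
  y <- 16.38 * log(age) + 16.85
  fit <- fit_log_model(age, y)
  expect_equal(fit$beta_age, 16.38, tolerance = 1e-8)
  expect_equal(fit$intercept, 16.85, tolerance = 1e-8)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  # null data: coefficient near zero on average
  set.seed(31)
  zs <- replicate(100, fit_log_model(age, rnorm(119))$z)
  expect_lt(abs(mean(zs)), 0.3)
})

test_that("Bonferroni thresholds reproduce the printed voxel-wise pairing", {
  thr <- bonferroni_threshold(0.05, 144237)
  expect_equal(thr$p_threshold, 3.47e-7, tolerance = 0.002)
  expect_equal(thr$z_threshold, 5.1, tolerance = 0.005)
  thr1 <- bonferroni_threshold(0.05, 1)
  expect_equal(thr1$p_threshold, 0.05)
  expect_equal(thr1$z_threshold, qnorm(0.975), tolerance = 1e-12)
  expect_equal(round(bonferroni_threshold(0.05, 3)$p_threshold, 4), 0.0167)
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("voxel-wise age effects match a per-voxel lm loop", {
  set.seed(41)
  n <- 30
  age <- runif(n, 1.4, 28)
  covs <- data.frame(sex = rbinom(n, 1, 0.5), motion = runif(n, 0, 0.4))
  X <- matrix(rnorm(20 * n, 50, 8), 20, n)
  X[1:10, ] <- X[1:10, ] + 10 * matrix(log(age), 10, n, byrow = TRUE)
  em <- voxelwise_age_effects(X, age, covs)
  for (v in c(1, 5, 15, 20)) {
    ref <- fit_log_model(age, X[v, ], covs)
    expect_equal(em$beta[v], ref$beta_age, tolerance = 1e-10)
    expect_equal(em$z[v], ref$z, tolerance = 1e-8)
    expect_equal(em$r[v], ref$r, tolerance = 1e-8)
  }
  # constant voxel is flagged with Z = 0
  X[3, ] <- 42
  em2 <- voxelwise_age_effects(X, age, covs)
  expect_true(em2$flagged[3])
  expect_equal(em2$z[3], 0)
})

test_that("null voxels exceed the nominal threshold at about the alpha rate", {
  set.seed(51)
  n <- 40
  age <- sample(runif(n, 1.4, 28))
  X <- matrix(rnorm(20000 * n), 20000, n)
  em <- voxelwise_age_effects(X, age)
  rate <- mean(abs(em$z) > qnorm(0.975))
  expect_lt(abs(rate - 0.05), 0.012)
  # Bonferroni-corrected exceedances are rare under the null
  z_thr <- bonferroni_threshold(0.05, 20000)$z_threshold
  expect_lte(sum(abs(em$z) > z_thr), 3)
})

test_that("fitted map stacks cover 1-28 months at the published covariates", {
  age <- seq(1.4, 28, length.out = 76)
  y <- 16.38 * log(age) + 16.85
  em <- voxelwise_age_effects(rbind(y, y), age)
  stack <- predict_map_stack(em, covariate_values = list())
  expect_equal(ncol(stack), 55)
  expect_equal(attr(stack, "ages"), seq(1, 28, by = 0.5))
  expect_equal(unname(stack[1, 1]), 16.85, tolerance = 1e-8)  # ln(1) = 0
  expect_true(all(diff(stack[1, ]) > 0))
  expect_error(predict_map_stack(em, ages = c(0, 2), covariate_values = list()),
               "positive")
})

test_that("rate maps are the derivative of the logarithmic fit", {
  r <- rate_maps(16.38, ages = c(6, 12))
  expect_equal(r[1, 2], 16.38 / 12)
  expect_equal(round(r[1, 2], 3), 1.365)
  expect_equal(r[1, 1], 2 * r[1, 2])  # rate at 6 months doubles 12 months
  full <- rate_maps(c(10, 20))
  expect_true(all(diff(full[1, ]) < 0))
  expect_error(rate_maps(10, ages = -1), "positive")
})
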