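test_that("noiseless two-phase data is recovered exactly", {
  age <- seq(1.4, 28, length.out = 119)
  psi <- 10
  y <- 18 + 3.52 * pmin(age, psi) + 0.43 * pmax(age - psi, 0)
  fit <- suppressWarnings(fit_segmented(age, y, 1))
  expect_equal(fit$psi, 10, tolerance = 1e-6)
  expect_equal(fit$slopes, c(3.52, 0.43), tolerance = 1e-6)
  expect_equal(fit$intercept, 18, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-12)
})

test_that("the fitted piecewise function is continuous at the breakpoint", {
  set.seed(61)
  for (i in 1:5) {
    age <- runif(80, 1.4, 28)
    y <- 20 + 3 * pmin(age, 11) + 0.5 * pmax(age - 11, 0) + rnorm(80, 0, 4)
    fit <- suppressWarnings(fit_segmented(age, y, 1))
    left <- fit$intercept + fit$slopes[1] * fit$psi
    right <- fit$intercept + fit$slopes[1] * fit$psi +
      (fit$slopes[2] - fit$slopes[1]) * 0
    expect_lt(abs(left - right), 1e-8)
    # equivalently: prediction from phase-2 parameterization agrees
    phase2_at_psi <- fit$intercept + fit$slopes[1] * fit$psi +
      fit$slopes[2] * (fit$psi - fit$psi)
    expect_lt(abs(left - phase2_at_psi), 1e-8)
  }
})

test_that("iterative estimates agree with a brute-force profile search", {
  set.seed(71)
  for (i in 1:20) {
    age <- sort(runif(60, 1.4, 28))
    psi0 <- runif(1, 6, 16)
    y <- 20 + runif(1, 2, 5) * pmin(age, psi0) +
      runif(1, 0, 1) * pmax(age - psi0, 0) + rnorm(60, 0, 3)
    fit <- suppressWarnings(fit_segmented(age, y, 1))
    oracle <- grid_psi_oracle(age, y)
    expect_lt(abs(fit$psi - oracle), 0.051)
    # and the returned optimum is no worse than the grid optimum
    Xo <- cbind(1, age, pmax(age - oracle, 0))
    rss_o <- sum(stats::lm.fit(Xo, y)$residuals^2)
    expect_lte(fit$rss, rss_o + 1e-6)
  }
})

test_that("nested model comparison gives an extra-sum-of-squares F test", {
  d <- generate_global_cohort(119, "biphasic", seed = 81)
  f0 <- fit_segmented(d$age, d$global_cbf, 0)
  f1 <- suppressWarnings(fit_segmented(d$age, d$global_cbf, 1))
  cmp <- compare_segmented(f0, f1)
  expect_equal(cmp$df1, 2)
  expect_equal(cmp$df2, 119 - 4)
  expect_lt(cmp$p, 0.001)   # strongly biphasic data
  self <- compare_segmented(f0, f0_complex <- f1)
  expect_error(compare_segmented(f1, f0), "more parameters")
  d2 <- generate_global_cohort(60, "biphasic", seed = 82)
  expect_error(compare_segmented(fit_segmented(d2$age, d2$global_cbf, 0), f1),
               "identical data")
})

test_that("identical fits compare with F = 0 and p = 1", {
  age <- seq(1, 28, length.out = 50)
  y <- 2 * age + rnorm(50)
  f0 <- fit_segmented(age, y, 0)
  f0b <- f0
  f0b$n_params <- f0$n_params + 2L  # same RSS, formally richer
  cmp <- compare_segmented(f0, f0b)
  expect_equal(cmp$F, 0)
  expect_equal(cmp$p, 1)
})

test_that("breakpoint-count selection matches the generating structure", {
  set.seed(91)
  age <- sort(runif(119, 1.4, 28))
  # pure linear -> 0 breakpoints
  lin <- 20 + 2 * age + rnorm(119, 0, 5)
  expect_equal(suppressWarnings(select_n_breakpoints(age, lin))$n_breakpoints,
               0L)
  # biphasic generator -> 1 breakpoint
  d <- generate_global_cohort(119, "biphasic", seed = 91)
  expect_equal(
    suppressWarnings(select_n_breakpoints(d$age, d$global_cbf))$n_breakpoints,
    1L)
  # three sharply different phases -> 2 breakpoints
  y3 <- 10 + 6 * pmin(age, 8) + 0.2 * pmax(pmin(age, 18) - 8, 0) +
    4 * pmax(age - 18, 0) + rnorm(119, 0, 1.5)
  expect_equal(suppressWarnings(select_n_breakpoints(age, y3))$n_breakpoints,
               2L)
})

test_that("covariates are residualized out before segmented fitting", {
  set.seed(101)
  age <- sort(runif(100, 1.4, 28))
  sex <- rbinom(100, 1, 0.5)
  y <- 18 + 3.5 * pmin(age, 10.75) + 0.4 * pmax(age - 10.75, 0) +
    6 * sex + rnorm(100, 0, 2)
  fit <- suppressWarnings(fit_segmented(age, y, 1,
                                        covariates = data.frame(sex = sex)))
  expect_equal(fit$psi, 10.75, tolerance = 1.5)
})

test_that("degenerate phases and out-of-range requests error", {
  age <- seq(1, 28, length.out = 30)
  y <- 2 * age + rnorm(30)
  expect_error(fit_segmented(age[1:5], y[1:5], 1), "few observations")
  expect_error(suppressWarnings(fit_segmented(age, y, 1, init_psi = 27.9)),
               NA)  # a bad start falls back, it does not error
  expect_error(fit_segmented(age, y, 4), "between 0 and 3")
})

test_that("delta-method confidence intervals cover the true breakpoint", {
  psis <- numeric(0)
  covered <- logical(0)
  for (s in 1:200) {
    d <- generate_global_cohort(119, "biphasic", seed = 7000 + s)
    fit <- suppressWarnings(fit_segmented(d$age, d$global_cbf, 1))
    psis <- c(psis, fit$psi)
    covered <- c(covered, fit$psi_ci[1, 1] <= 10.75 &&
                   10.75 <= fit$psi_ci[1, 2])
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.995)
  expect_equal(median(psis), 10.75, tolerance = 1.2)
})

test_that("voxel-wise breakpoints follow the limbic-sensorimotor-association order", {
  co <- small_cohort(seed = 8, n = 60)
  vb <- suppressWarnings(
    voxelwise_breakpoints(co$rcbf, co$cohort_table$age, co$voxel_labels))
  med <- vapply(vb$by_cluster, median, numeric(1))
  expect_lt(med[["1"]], med[["2"]])   # limbic before sensorimotor
  expect_lt(med[["2"]], med[["3"]])   # sensorimotor before frontoparietal
  expect_lt(vb$n_failed / nrow(co$rcbf), 0.2)
  # identical voxels give a degenerate single-value histogram
  age <- seq(1.4, 28, length.out = 40)
  y <- 15 + 4 * pmin(age, 9) + 0.5 * pmax(age - 9, 0)
  same <- rbind(y, y, y)
  vb2 <- suppressWarnings(voxelwise_breakpoints(same, age,
                                                labels = c(1, 1, 1)))
  expect_equal(length(unique(round(vb2$psi, 6))), 1)
})
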