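test_that("generation is deterministic given the seed", {
  a <- generate_cohort(generator_config(seed = 123, n_subjects = 20,
                                        grid_shape = c(10, 12, 10)))
  b <- generate_cohort(generator_config(seed = 123, n_subjects = 20,
                                        grid_shape = c(10, 12, 10)))
  expect_identical(a$rcbf, b$rcbf)
  expect_identical(a$cohort_table, b$cohort_table)
  expect_identical(a$motion, b$motion)
  c <- generate_cohort(generator_config(seed = 124, n_subjects = 20,
                                        grid_shape = c(10, 12, 10)))
  expect_false(identical(a$rcbf, c$rcbf))
})

test_that("cohort invariants hold: ages, positivity, label partition", {
  co <- generate_cohort(generator_config(seed = 6))
  ages <- co$cohort_table$age
  expect_true(all(ages >= 1.4 & ages <= 28))
  expect_equal(mean(ages), 12.5, tolerance = 2.5)
  expect_true(all(co$rcbf > 0))
  expect_equal(sort(unique(co$voxel_labels)), 1:3)
  expect_equal(length(co$voxel_labels), sum(co$mask))
  expect_equal(sum(co$labels > 0), sum(co$mask))
  fr <- as.vector(table(co$voxel_labels)) / length(co$voxel_labels)
  expect_equal(fr, c(0.25, 0.35, 0.40), tolerance = 0.01)
})

test_that("the logarithmic curve evaluates to 33.23 at age e", {
  d <- generate_global_cohort(119, "logarithmic", residual_sd = 0, seed = 2)
  expect_equal(d$global_cbf, d$truth)
  fit <- fit_log_model(d$age, d$global_cbf)
  at_e <- fit$intercept + fit$beta_age * 1  # ln(e) = 1
  expect_equal(at_e, 33.23, tolerance = 1e-6)
})

test_that("per-cluster trajectories break at 6.71, 7.69, 10.36 months", {
  cp <- generator_config()$cluster_params
  expect_equal(cp$psi, c(6.71, 7.69, 10.36))
  for (i in 1:3) {
    a <- seq(1.4, 28, by = 0.01)
    y <- cluster_trajectory(cp[i, ], a)
    slopes <- diff(y) / diff(a)
    change_at <- a[which.max(abs(diff(slopes))) + 1]
    expect_equal(change_at, cp$psi[i], tolerance = 0.02)
    expect_true(all(y > 0))
  }
})

test_that("phase-contrast generation inverts the flux equation", {
  fl <- generate_pc_measurement(56.6, 500)
  expect_equal(sum(fl), 56.6 * 1.06 * 500 / 100)
  expect_equal(sum(fl), 299.98, tolerance = 0.01)
  expect_equal(sum(generate_pc_measurement(0, 500)), 0)
  # round trip through quantification
  expect_equal(global_cbf_from_pc(fl, 500), 56.6, tolerance = 1e-12)
  expect_error(generate_pc_measurement(50, -1), "positive")
})

test_that("cohort PC fluxes reproduce each subject's global CBF exactly", {
  co <- generate_cohort(generator_config(seed = 13, n_subjects = 15,
                                         grid_shape = c(10, 10, 10)))
  for (j in 1:15) {
    g <- global_cbf_from_pc(as.numeric(co$pc_fluxes[j, 1:4]),
                            co$pc_fluxes$brain_volume[j])
    expect_equal(g, co$cohort_table$global_cbf[j], tolerance = 1e-9)
  }
})

test_that("noiseless ASL series round-trip to the truth map", {
  co <- generate_cohort(generator_config(seed = 14, n_subjects = 5,
                                         grid_shape = c(10, 10, 10)),
                        include_asl = TRUE)
  for (j in 1:5) {
    asl <- co$asl[[j]]
    dm <- compute_delta_m(asl$control, asl$label)
    map <- rcbf_from_asl(dm, asl$m0)
    rel <- abs(map$values - co$rcbf[, j]) / co$rcbf[, j]
    expect_lt(max(rel), 1e-9)
  }
  expect_error(generate_asl_series(c(1, 2, 3), n_pairs = 0), ">= 1")
  expect_error(generate_asl_series(c(-1, 2)), "positive")
})

test_that("a translated volume shows its displacement in motion QC", {
  truth <- rep(50, 20)
  prof <- matrix(0, 20, 6)
  prof[5, 4:6] <- c(0.6, 0, 0.8)   # 1 mm translation
  asl <- generate_asl_series(truth, motion_profile = prof)
  rel <- relative_rms_displacement(asl$motion)
  expect_equal(rel[5], 1.0)
  expect_equal(rel[6], 1.0)        # moving back displaces again
  expect_equal(sum(rel > 0), 2)
  expect_equal(ncol(asl$control), 10)   # default 10 control/label pairs
})

test_that("behavior scores carry the configured partial correlation", {
  cors <- vapply(1:10, function(s) {
    co <- generate_cohort(generator_config(seed = 400 + s))
    tab <- co$cohort_table
    cm <- colMeans(co$rcbf[co$voxel_labels == 2, ])
    res_c <- residuals(lm(cm ~ log(tab$age)))
    res_s <- residuals(lm(tab$motor ~ log(tab$age)))
    cor(res_c, res_s)
  }, numeric(1))
  expect_equal(mean(cors), 0.5, tolerance = 0.1)
  co <- generate_cohort(generator_config(seed = 7))
  expect_equal(mean(co$cohort_table$motor), 100, tolerance = 8)
  expect_equal(sd(co$cohort_table$motor), 15, tolerance = 6)
})

test_that("zero behavior effect leaves scores independent of rCBF", {
  co <- generate_cohort(generator_config(seed = 19, behavior_effect = 0))
  tab <- co$cohort_table
  cm <- colMeans(co$rcbf[co$voxel_labels == 2, ])
  res_c <- residuals(lm(cm ~ log(tab$age)))
  res_s <- residuals(lm(tab$motor ~ log(tab$age)))
  expect_gt(cor.test(res_c, res_s)$p.value, 0.01)
})

test_that("reference maps correlate perfectly with their own age pattern", {
  co <- small_cohort(seed = 20)
  ref <- generate_reference_map(co, age = 28, noise_sd = 0)
  pattern <- vapply(seq_len(nrow(co$cluster_params)), function(i)
    cluster_trajectory(co$cluster_params[i, ], 28), numeric(1))
  expect_equal(ref, pattern[co$voxel_labels])
  # diverging clusters: late pattern differs more from the early one
  early <- generate_reference_map(co, age = 1.5)
  expect_lt(cor(early, ref), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_subjects = 0), "configuration error")
  expect_error(generator_config(cluster_fractions = c(limbic = 0.5,
                                                      sensorimotor = 0.2,
                                                      frontoparietal = 0.2)),
               "sum to 1")
  expect_error(
    generate_behavior_scores(matrix(1, 4, 3), c(1, 1, 2, 2),
                             c(2, 5, 9), c("a", "b"),
                             loading = list(motor = "nope")),
    "unknown cluster")
})

test_that("logarithmic age slopes order along the cortical hierarchy", {
  betas <- sapply(1:5, function(s) {
    co <- generate_cohort(generator_config(seed = 500 + s))
    a <- co$cohort_table$age
    vapply(1:3, function(i)
      fit_log_model(a, colMeans(co$rcbf[co$voxel_labels == i, ]))$beta_age,
      numeric(1))
  })
  m <- rowMeans(betas)
  expect_gt(m[3], m[2])   # frontoparietal steepest
  expect_gt(m[2], m[1])   # sensorimotor above limbic
  expect_gt(m[1], 0)
})
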