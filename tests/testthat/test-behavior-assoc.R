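make_behavior_data <- function(seed, n = 49, effect = 0) {
  set.seed(seed)
  age <- runif(n, 1.4, 28)
  sex <- rbinom(n, 1, 0.5)
  motion <- abs(rnorm(n, 0.22, 0.1))
  ses <- rnorm(n, 40, 12)
  resid <- rnorm(n)
  rcbf <- 30 + 12 * log(age) + 8 * resid
  score <- 100 + 15 * (effect * resid +
                         sqrt(1 - effect^2) * rnorm(n))
  list(rcbf = rcbf, score = score, age = age, sex = sex, motion = motion,
       ses = ses)
}

test_that("the behavior GAM controls its type-I error near alpha", {
  hits <- replicate(250, {
    d <- make_behavior_data(sample.int(1e6, 1))
    abs(fit_gam_behavior(d$rcbf, d$score, d$age, d$sex, d$motion,
                         d$ses)$t) > 2.02
  })
  # GCV-selected smoothing is known to be slightly anticonservative, so
  # the empirical rate sits near, not exactly at, the nominal level
  expect_lt(abs(mean(hits) - 0.05), 0.05)
  expect_gt(mean(hits), 0.005)
})

test_that("a loaded behavior effect yields the predicted t magnitude", {
  # partial r = 0.5 at ~43 residual df: |t| ~ 0.5 sqrt(43)/sqrt(0.75) ~ 3.7
  ts <- replicate(40, {
    d <- make_behavior_data(sample.int(1e6, 1), effect = 0.5)
    fit_gam_behavior(d$rcbf, d$score, d$age, d$sex, d$motion, d$ses)$t
  })
  expect_equal(mean(ts), 3.7, tolerance = 1.0)
  expect_gt(mean(abs(ts) > 2.02), 0.8)
})

test_that("the age spline absorbs a logarithmic age effect", {
  diffs <- vapply(1:20, function(s) {
    d <- make_behavior_data(1000 + s)
    gam_t <- fit_gam_behavior(d$rcbf, d$score, d$age, d$sex, d$motion,
                              d$ses)$t
    # oracle with the true log-age form entered parametrically
    oracle <- summary(lm(d$rcbf ~ d$score + log(d$age) + d$sex + d$motion +
                           d$ses))$coefficients["d$score", "t value"]
    gam_t - oracle
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.15)
  expect_lt(max(abs(diffs)), 0.8)
})

test_that("with a huge smoothing penalty the GAM reduces to a linear age model", {
  d <- make_behavior_data(321)
  fit <- mgcv::gam(rcbf ~ score + s(age, bs = "cr", k = 5) + sex + motion +
                     ses, data = as.data.frame(d), sp = 1e8)
  t_pen <- summary(fit)$p.table["score", "t value"]
  t_lin <- summary(lm(rcbf ~ score + age + sex + motion + ses,
                      data = as.data.frame(d)))$coefficients["score",
                                                             "t value"]
  expect_equal(t_pen, t_lin, tolerance = 0.02)
})

test_that("voxel-wise t-maps localize a cluster-loaded behavior effect", {
  co <- generate_cohort(generator_config(seed = 17))
  tab <- co$cohort_table
  sub <- 1:49
  tm <- voxelwise_behavior_tmap(co$rcbf[, sub], tab$motor[sub],
                                tab$age[sub], tab$sex[sub], tab$mrd[sub],
                                tab$ses[sub])
  supra <- tm$t > 2.02
  in_sm <- co$voxel_labels == 2   # motor loads on the sensorimotor cluster
  odds <- (mean(supra[in_sm]) / (1 - mean(supra[in_sm]))) /
    ((mean(supra[!in_sm]) + 1e-6) / (1 - mean(supra[!in_sm]) + 1e-6))
  expect_gt(odds, 5)
})

test_that("cluster extraction matches a brute-force flood fill", {
  set.seed(85)
  for (i in 1:5) {
    tmap <- array(rnorm(10 * 9 * 8, 0, 1.5), c(10, 9, 8))
    got <- extract_clusters(tmap, t_threshold = 2, min_extent = 1)
    oracle_lab <- floodfill_oracle(tmap > 2)
    sizes_oracle <- sort(as.integer(table(oracle_lab[oracle_lab > 0])),
                         decreasing = TRUE)
    sizes_got <- vapply(got, `[[`, numeric(1), "size")
    expect_equal(as.integer(sizes_got), sizes_oracle)
  }
})

test_that("the minimum cluster extent drops undersized blobs", {
  tmap <- array(0, c(12, 12, 12))
  tmap[2:6, 2:6, 2:5] <- 5          # 100-voxel blob
  tmap[8:12, 8:12, 8:11] <- 5       # another 100-voxel blob
  tmap[8:12, 8:12, 11] <- 0         # shrink the second to 75
  cl <- extract_clusters(tmap, t_threshold = 2.02, min_extent = 100)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 100)
  expect_equal(cl[[1]]$volume_mm3, 800)   # 100 voxels x 8 mm^3
  expect_length(extract_clusters(array(0, c(5, 5, 5)), min_extent = 1), 0)
  expect_error(extract_clusters(array(0, c(0, 0, 0))), "non-empty")
})

test_that("clusters are annotated with their dominant parcel", {
  tmap <- array(0, c(6, 6, 6))
  tmap[1:3, 1:3, 1:3] <- 5
  parcels <- array("frontoparietal", c(6, 6, 6))
  parcels[1:3, , ] <- "limbic"
  cl <- extract_clusters(tmap, min_extent = 1, parcel_labels = parcels)
  expect_equal(cl[[1]]$parcel, "limbic")
})

test_that("cluster-level association applies the domain Bonferroni rule", {
  d <- make_behavior_data(55, effect = 0.6)
  res <- cluster_level_assoc(list(loaded = d$rcbf), d$score, d$age, d$sex,
                             d$motion, d$ses)
  expect_equal(res$p_threshold, 0.05 / 3, tolerance = 1e-12)
  expect_equal(round(res$p_threshold, 4), 0.0167)
  expect_true(res$significant[1])
})

test_that("a loaded cluster is detected in most simulated cohorts", {
  hits <- vapply(1:15, function(s) {
    co <- generate_cohort(generator_config(seed = 300 + s))
    tab <- co$cohort_table
    sub <- 1:49
    cm <- colMeans(co$rcbf[co$voxel_labels == 2, sub])
    res <- cluster_level_assoc(list(sm = cm), tab$motor[sub], tab$age[sub],
                               tab$sex[sub], tab$mrd[sub], tab$ses[sub])
    res$significant[1]
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("river summaries normalize significant voxels within domains", {
  mk <- function(size, parcel) list(voxels = NULL, size = size,
                                    volume_mm3 = size * 8, peak_t = 3,
                                    parcel = parcel)
  dom <- list(motor = list(mk(75, "sensorimotor"), mk(25, "limbic")),
              language = list(mk(40, "frontoparietal")),
              cognitive = list())
  rs <- behavior_river_summary(dom, parcels = c("limbic", "sensorimotor",
                                                "frontoparietal"))
  expect_equal(rs$proportions["motor", ], c(limbic = 0.25,
                                            sensorimotor = 0.75,
                                            frontoparietal = 0))
  expect_equal(sum(rs$proportions["language", ]), 1)
  expect_equal(rs$empty_domains, "cognitive")
})
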