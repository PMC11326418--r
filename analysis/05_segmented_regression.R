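#!/usr/bin/env Rscript
# Breakpoint stage: one-breakpoint segmented regression of global CBF,
# breakpoint-count selection by ANOVA, per-cluster breakpoints of the
# regional cohort, and the voxel-wise breakpoint histograms.
suppressPackageStartupMessages(library(infantflow))

gbi <- read_tsv("results/global_cohort_biphasic.tsv")
co <- readRDS("results/regional_cohort.rds")
a <- co$cohort_table$age

sel <- suppressWarnings(select_n_breakpoints(gbi$age, gbi$global_cbf))
cat(sprintf("global CBF: %d breakpoint(s) selected\n", sel$n_breakpoints))
fit <- suppressWarnings(fit_segmented(gbi$age, gbi$global_cbf, 1))
cmp <- compare_segmented(fit_segmented(gbi$age, gbi$global_cbf, 0), fit)
cat(sprintf("  psi = %.2f months (95%% CI %.2f-%.2f), slopes %.2f / %.2f\n",
            fit$psi, fit$psi_ci[1, 1], fit$psi_ci[1, 2],
            fit$slopes[1], fit$slopes[2]))
cat(sprintf("  vs linear: F(%d,%d) = %.2f, p = %.2g\n",
            cmp$df1, cmp$df2, cmp$F, cmp$p))

rows <- lapply(seq_along(co$cluster_names), function(i) {
  cm <- colMeans(co$rcbf[co$voxel_labels == i, ])
  f <- suppressWarnings(fit_segmented(a, cm, 1))
  data.frame(cluster = co$cluster_names[i], psi = f$psi,
             ci_low = f$psi_ci[1, 1], ci_high = f$psi_ci[1, 2],
             slope1 = f$slopes[1], slope2 = f$slopes[2])
})
cl <- do.call(rbind, rows)
write_tsv(cl, "results/cluster_breakpoints.tsv")
cat("\nper-cluster breakpoints (months):\n")
print(cl, row.names = FALSE)

vb <- suppressWarnings(voxelwise_breakpoints(co$rcbf, a, co$voxel_labels))
hist_tab <- do.call(rbind, lapply(names(vb$by_cluster), function(l)
  data.frame(cluster = co$cluster_names[as.integer(l)],
             psi = vb$by_cluster[[l]])))
write_tsv(hist_tab, "results/voxel_breakpoints.tsv")
med <- vapply(vb$by_cluster, median, numeric(1))
cat(sprintf("\nvoxel-wise breakpoint medians: %s (%d voxels failed to fit)\n",
            paste(sprintf("%s %.1f", co$cluster_names, med),
                  collapse = ", "), vb$n_failed))
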