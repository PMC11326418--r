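#!/usr/bin/env Rscript
# Build the synthetic study cohorts every later stage analyzes:
#  - a global-CBF cohort (n = 119) from the logarithmic growth curve
#  - a global-CBF cohort (n = 119) from the anchored biphasic curve
#  - a regional cohort (n = 76) of voxel-wise rCBF maps with three
#    ground-truth clusters (limbic / sensorimotor / frontoparietal)
suppressPackageStartupMessages(library(infantflow))

seed <- 20260920L
dir.create("results", showWarnings = FALSE)

glog <- generate_global_cohort(119, "logarithmic", seed = seed)
gbi <- generate_global_cohort(119, "biphasic", seed = seed + 1)
cfg <- generator_config(seed = seed + 2)
co <- generate_cohort(cfg)

write_tsv(glog, "results/global_cohort_logarithmic.tsv")
write_tsv(gbi, "results/global_cohort_biphasic.tsv")
write_tsv(co$cohort_table, "results/regional_cohort.tsv")
write_mask_nifti(co$mask, "results/mask.nii.gz", cfg$voxel_size_mm)
write_map_nifti(array(as.double(co$labels), dim(co$labels)),
                "results/truth_labels.nii.gz",
                voxel_size_mm = cfg$voxel_size_mm)
write_config(pipeline_config(seed = seed,
                             generator = list(seed = cfg$seed)),
             "results/config.yaml")
saveRDS(co, "results/regional_cohort.rds")  # reused by later stages

cat(sprintf("global cohorts: n = %d, ages %.1f-%.1f months\n",
            nrow(glog), min(glog$age), max(glog$age)))
cat(sprintf("age-CBF correlation (logarithmic cohort): r = %.3f\n",
            cor(log(glog$age), glog$global_cbf)))
cat(sprintf("regional cohort: %d masked voxels, cluster sizes %s\n",
            nrow(co$rcbf), paste(table(co$voxel_labels), collapse = "/")))
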