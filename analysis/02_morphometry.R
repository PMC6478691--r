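#!/usr/bin/env Rscript
# Morphometry of the two section volumes: random 830 um ROI sampling on a
# mid-stack plane, subpleural/intralobular classification by median
# pleural distance, the six lymphatic measures per VOI, the control-vs-
# diseased Mann-Whitney comparison, and the distance regressions.

library(pulmolymph)

SEED <- 20260401L

study <- function(path, n_rois, seed) {
  vol <- read_volume(path)
  dm <- pleural_distance_map(vol)
  # sampling plane near the start of the stack, so the 500 um VOI depth
  # (38 voxels) fits inside the 44-voxel section
  zp <- 4L
  rois <- sample_rois(vol, zp, roi_side_um = 830, n_target = n_rois,
                      max_iter = 500L, seed = seed)
  message(sprintf("  %s: placed %d/%d ROIs (shortfall: %s)", basename(path),
                  nrow(rois), n_rois, attr(rois, "shortfall")))
  vois <- classify_rois(rois, vol, dm, threshold_um = 830, depth_um = 500)
  recs <- measure_vois(vol, vois)
  message(sprintf("  classes: %s",
                  paste(names(table(vois$region_class)),
                        table(vois$region_class), collapse = ", ")))
  recs
}

message("-- control section: 25 ROIs --")
ctrl <- study("results/control_section.nrrd", 25L, SEED + 10L)
write.csv(ctrl, "results/morphometry_control.csv", row.names = FALSE)

message("-- diseased section: 20 ROIs --")
dis <- study("results/diseased_section.nrrd", 20L, SEED + 11L)
write.csv(dis, "results/morphometry_diseased.csv", row.names = FALSE)

message("-- control vs diseased across the six measures (Mann-Whitney) --")
cmp <- compare_groups(ctrl, dis)
print(cmp, digits = 3)
write.csv(cmp, "results/group_comparison.csv", row.names = FALSE)

message("-- distance regressions on the control sample --")
reg_vf <- correlate_with_distance(ctrl$median_pleural_distance_um,
                                  ctrl$volume_fraction,
                                  measure = "volume_fraction")
reg_fd <- correlate_with_distance(ctrl$median_pleural_distance_um,
                                  ctrl$fractal_dimension,
                                  excluded = ctrl$excluded_fractal,
                                  measure = "fractal_dimension")
reg <- rbind(reg_vf, reg_fd)
print(reg, digits = 3)
message(sprintf(paste0("  volume fraction falls with pleural distance: ",
                       "r = %.2f (|r| = %.2f), p = %.2g, %d fractal VOIs ",
                       "excluded"),
                reg_vf$r, reg_vf$abs_r, reg_vf$p, reg_fd$n_excluded))
write.csv(reg, "results/distance_regression.csv", row.names = FALSE)

message("02_morphometry: done")
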