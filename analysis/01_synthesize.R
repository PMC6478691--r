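#!/usr/bin/env Rscript
# Build the synthetic study material: two wide "section" volumes standing
# in for the segmented control and diseased tissue blocks, and two cubic
# flow VOIs (intralobular- and subpleural-like opening topologies).
# All downstream analyses read from results/.

library(pulmolymph)

dir.create("results", showWarnings = FALSE)
SEED <- 20260401L

message("-- control-like section volume (pleura on y-) --")
control_spec <- synthetic_spec(
  shape = c(44L, 320L, 970L),          # 580 x 4224 x 12804 um at 13.2 um
  pleural_face = "y-",
  target_lymph_vf_at_pleura = 0.035,
  lymph_vf_gradient = -8e-6,
  openings = list(blood = c("z+" = 2L, "z-" = 2L, "x+" = 1L, "x-" = 1L),
                  lymph = c("z+" = 1L, "x-" = 1L)),
  seed = SEED)
t0 <- proc.time()
control <- generate_voi(control_spec)
message(sprintf("  generated in %.0f s: air %.2f, largest lymph component %.0f%%",
                (proc.time() - t0)[3], control$truth$air_fraction_realized,
                100 * control$truth$lymph_connected_fraction))
print(control$truth$bins[, c("bin", "depth_mid_um", "target_vf",
                             "realized_vf")])
write_volume(control$volume, "results/control_section.nrrd")
write.csv(control$truth$bins, "results/control_truth_bins.csv",
          row.names = FALSE)

message("-- diseased-like section volume (denser lymphatics) --")
diseased_spec <- synthetic_spec(
  shape = c(44L, 320L, 800L),
  pleural_face = "y-",
  target_lymph_vf_at_pleura = 0.06,    # disease: increased lymphatic volume
  lymph_vf_gradient = -8e-6,
  openings = list(blood = c("z+" = 2L, "z-" = 1L, "x+" = 1L),
                  lymph = c("z+" = 2L, "x-" = 1L)),
  seed = SEED + 1L)
diseased <- generate_voi(diseased_spec)
message(sprintf("  air %.2f, largest lymph component %.0f%%",
                diseased$truth$air_fraction_realized,
                100 * diseased$truth$lymph_connected_fraction))
write_volume(diseased$volume, "results/diseased_section.nrrd")

message("-- intralobular flow VOI (1 lymphatic + 4 blood inlets) --")
intra_spec <- synthetic_spec(shape = c(40L, 40L, 40L), seed = SEED + 2L)
intra <- generate_voi(intra_spec)
message(sprintf("  ring encircling a blood vessel in slices: %s",
                paste(ring_slices(intra$volume), collapse = ", ")))
write_volume(intra$volume, "results/intralobular_voi.nrrd")
write.csv(intra$truth$openings, "results/intralobular_openings.csv",
          row.names = FALSE)

message("-- subpleural flow VOI (6 lymphatic + 3 blood inlets) --")
sub_spec <- synthetic_spec(
  shape = c(40L, 40L, 40L),
  target_lymph_vf_at_pleura = 0.05,    # richer subpleural network
  openings = list(blood = c("z+" = 1L, "y+" = 1L, "x+" = 1L, "y-" = 1L),
                  lymph = c("z+" = 2L, "y+" = 2L, "x+" = 2L, "y-" = 1L)),
  seed = SEED + 3L)
subpl <- generate_voi(sub_spec)
write_volume(subpl$volume, "results/subpleural_voi.nrrd")
write.csv(subpl$truth$openings, "results/subpleural_openings.csv",
          row.names = FALSE)

message("01_synthesize: done; volumes and ground truth under results/")
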