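test_that("the generator is bitwise deterministic given the spec", {
  spec <- synthetic_spec(shape = c(32L, 32L, 32L), seed = 11L)
  g1 <- generate_voi(spec)
  g2 <- generate_voi(spec)
  expect_identical(g1$volume$labels, g2$volume$labels)
  expect_identical(g1$truth$bins, g2$truth$bins)
})

test_that("labels stay within the declared set and classes are disjoint", {
  g <- std_voi()
  expect_true(all(g$volume$labels %in% 0:4))
  # one label per voxel is structural; check the class masks partition
  m <- g$volume$labels
  expect_equal(sum(m == 0) + sum(m == 1) + sum(m == 2) + sum(m == 3) +
                 sum(m == 4), length(m))
})

test_that("requested openings are realized exactly on the right faces", {
  g <- std_voi()
  op <- g$truth$openings
  blood_in <- op[op$class == "blood" & op$face %in% c("z+", "y+", "x+"), ]
  lymph_in <- op[op$class == "lymph" & op$face %in% c("z+", "y+", "x+"), ]
  expect_equal(sum(blood_in$patches), 4L)  # four supply openings
  expect_equal(sum(lymph_in$patches), 1L)  # one lymphatic entry
  # no lumen voxels on unrequested faces (realized_openings lists all)
  expect_true(all(op$face %in% c("z+", "y+", "x+", "y-", "x-")))
})

test_that("realized volume fraction tracks the depth model within 20%", {
  g <- std_voi()
  b <- g$truth$bins
  expect_true(all(abs(b$realized_vf / b$target_vf - 1) < 0.2))
})

test_that("a flat depth profile lands inside the +/-20% band in every bin", {
  spec <- synthetic_spec(shape = c(40L, 40L, 40L),
                         target_lymph_vf_at_pleura = 0.02,
                         lymph_vf_gradient = 0, seed = 6L)
  g <- generate_voi(spec)
  expect_true(all(g$truth$bins$realized_vf >= 0.016 &
                    g$truth$bins$realized_vf <= 0.024))
})

test_that("the encircling ring contains blood in at least one slice", {
  g <- std_voi()
  expect_true(g$truth$encircling_ring)
  expect_gt(length(ring_slices(g$volume)), 0)
})

test_that("infeasible specs are rejected with named constraints", {
  expect_error(synthetic_spec(shape = c(16L, 32L, 32L)), "at least 32")
  expect_error(synthetic_spec(target_lymph_vf_at_pleura = 1.5), "fraction")
  expect_error(synthetic_spec(
    blood_tree = list(depth = 2L, root_radius_um = 2, taper = 0.75)),
    "radius below 1 voxel")
  expect_error(synthetic_spec(
    openings = list(blood = c("z+" = 50L), lymph = c("z+" = 1L))),
    "do not fit")
  expect_error(synthetic_spec(
    openings = list(blood = c("z-" = 1L), lymph = c("z+" = 1L))),
    "pleural face")
  expect_error(generate_voi(synthetic_spec(lymph_vf_gradient = -1e-3,
                                           shape = c(48L, 48L, 48L))),
               "negative")
})

test_that("cohorts have the promised size, trend and determinism", {
  base <- cohort_base_spec()
  coh <- generate_cohort(base, n_voi = 5L, gradient = -8e-6, noise_sd = 0,
                         seed = 21L)
  expect_length(coh$volumes, 5L)
  expect_equal(nrow(coh$truth), 5L)
  # noiseless negative gradient: true VF non-increasing with distance
  expect_true(all(diff(coh$truth$true_vf[order(coh$truth$distance_um)]) <= 0))
  coh0 <- generate_cohort(base, n_voi = 4L, gradient = 0, noise_sd = 0,
                          seed = 21L)
  expect_equal(length(unique(coh0$truth$true_vf)), 1L)
  expect_error(generate_cohort(base, n_voi = 5L, gradient = -1e-4,
                               seed = 1L), "negative")
  expect_error(generate_cohort(base, n_voi = 2L), "n_voi")
  coh2 <- generate_cohort(base, n_voi = 5L, gradient = -8e-6, noise_sd = 0,
                          seed = 21L)
  expect_identical(coh$volumes[[3]]$labels, coh2$volumes[[3]]$labels)
})
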