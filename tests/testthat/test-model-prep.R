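test_that("nearest-neighbour upsampling preserves class fractions exactly", {
  g <- std_voi()
  m1 <- prepare_model_volume(g$volume, voi = NULL, upsample = 1L,
                             median_window = 1L)
  m3 <- prepare_model_volume(g$volume, voi = NULL, upsample = 3L,
                             median_window = 1L)
  n1 <- prod(dim(m1$interstitium)); n3 <- prod(dim(m3$interstitium))
  for (cl in c("interstitium", "blood", "lymph", "air"))
    expect_equal(sum(m3[[cl]]) / n3, sum(m1[[cl]]) / n1)
  expect_equal(m3$voxel_pitch_um, g$volume$voxel_pitch_um / 3)
})

test_that("masks are pairwise disjoint and jointly cover the grid", {
  g <- std_voi()
  m <- prepare_model_volume(g$volume, voi = NULL, upsample = 1L,
                            median_window = 3L)
  tot <- m$interstitium + m$blood + m$lymph + m$air
  expect_true(all(tot == 1L))
})

test_that("an isolated lumen island is pruned; 1 voxel -> 27 after x3", {
  a <- array(1L, c(12, 12, 12))
  a[6, 6, 6] <- 2L          # 1-voxel blood island in the interior
  a[, 2, 2] <- 2L           # a face-connected blood column stays
  vol <- label_volume(a, 10)
  m <- prepare_model_volume(vol, voi = NULL, upsample = 3L,
                            median_window = 1L)
  expect_equal(unname(m$provenance$removed_component_voxels["blood"]), 27L)
  # the face-connected column survives (x3 voxels)
  expect_equal(sum(m$blood), 12L * 27L)
})

test_that("pruning never removes voxels connected to a face", {
  g <- std_voi()
  m <- prepare_model_volume(g$volume, voi = NULL, upsample = 1L,
                            median_window = 3L)
  ns <- asNamespace("pulmolymph")
  for (cl in c("blood", "lymph")) {
    msk <- m[[cl]]
    if (!any(msk)) next
    dd <- dim(msk)
    cc <- array(ns$.cpp_label_components(as.vector(msk), dd, 26L), dd)
    onface <- setdiff(unique(c(cc[1, , ], cc[dd[1], , ], cc[, 1, ],
                               cc[, dd[2], ], cc[, , 1], cc[, , dd[3]])), 0L)
    expect_true(all(cc[msk] %in% onface))
  }
})

test_that("overlap after filtering resolves lymph over blood over tissue", {
  a <- array(1L, c(12, 12, 12))
  a[, 5, 5] <- 2L
  a[, 5:6, 5] <- 3L         # lymph written over part of the blood column
  vol <- label_volume(a, 10)
  m <- prepare_model_volume(vol, voi = NULL, upsample = 1L,
                            median_window = 1L)
  expect_false(any(m$blood & m$lymph))
  expect_true(all(m$lymph[, 5, 5]))   # lymph won the contested voxels
})

test_that("shrinkage scaling doubles the pitch without touching voxels", {
  g <- std_voi()
  m1 <- prepare_model_volume(g$volume, voi = NULL, upsample = 1L,
                             median_window = 1L)
  m2 <- prepare_model_volume(g$volume, voi = NULL, upsample = 1L,
                             median_window = 1L, shrinkage_scale = 2)
  expect_equal(m2$voxel_pitch_um, 2 * m1$voxel_pitch_um)
  expect_identical(m2$blood, m1$blood)
  expect_identical(m2$lymph, m1$lymph)
})

test_that("errors: even window, bad upsample, VOI outside the volume", {
  g <- std_voi()
  expect_error(prepare_model_volume(g$volume, median_window = 2L), "odd")
  expect_error(prepare_model_volume(g$volume, upsample = 0L), "positive")
  voi <- data.frame(y0 = 30L, x0 = 30L, side_vox = 20L, z0 = 30L)
  expect_error(prepare_model_volume(g$volume, voi = voi, upsample = 1L),
               "outside")
})

test_that("openings split into inlets on distal faces and outlets elsewhere", {
  case <- std_flow_case()
  pat <- case$boundaries$patches
  expect_setequal(case$boundaries$distal_faces, c("z+", "y+", "x+"))
  expect_equal(sum(pat$class == "blood" & pat$role == "inlet"), 4L)
  expect_equal(sum(pat$class == "lymph" & pat$role == "inlet"), 1L)
  expect_gte(sum(pat$role == "outlet"), 1L)
  # inlet/outlet is a partition of all boundary lumen faces
  cells <- case$boundaries$cells
  expect_true(all(cells$role %in% c("inlet", "outlet")))
  expect_false(any(duplicated(cells[, c("class", "face", "cell")])))
})

test_that("the subpleural opening topology (6 lymph, 3 blood) is realized", {
  sp <- synthetic_spec(shape = c(40L, 40L, 40L),
                       openings = list(blood = c("z+" = 1L, "y+" = 1L,
                                                 "x+" = 1L, "y-" = 1L),
                                       lymph = c("z+" = 2L, "y+" = 2L,
                                                 "x+" = 2L, "y-" = 1L)),
                       seed = 8L)
  g <- generate_voi(sp)
  m <- prep1(g$volume)
  b <- identify_vessel_openings(m)
  pat <- b$patches
  expect_equal(sum(pat$class == "lymph" & pat$role == "inlet"), 6L)
  expect_equal(sum(pat$class == "blood" & pat$role == "inlet"), 3L)
})

test_that("a pleura-to-distal tube gets one inlet and one outlet", {
  tb <- generate_validation_geometry("tube", shape = c(32L, 20L, 20L),
                                     radius = 4)
  m <- prep1(tb)
  b <- identify_vessel_openings(m, pleural_direction = "z-")
  pat <- b$patches
  expect_equal(pat$role[pat$face == "z+"], "inlet")
  expect_equal(pat$role[pat$face == "z-"], "outlet")
  expect_equal(nrow(pat), 2L)
})

test_that("a vessel class with no distal opening is an unforced model", {
  # tube reaching only the pleural face: no inlet patch anywhere distal
  a <- array(1L, c(20, 16, 16))
  a[1:10, 8, 8] <- 2L
  ns <- asNamespace("pulmolymph")
  arr <- ns$rasterize_brush(a, cbind(1:10, 8, 8), 2, 2L, clamp = TRUE)
  m <- prep1(label_volume(arr, 10))
  expect_error(identify_vessel_openings(m, pleural_direction = "z-"),
               "no inlet")
})
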