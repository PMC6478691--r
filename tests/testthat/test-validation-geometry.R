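test_that("validation geometries match their analytic definitions", {
  sl <- generate_validation_geometry("slab", shape = c(16L, 16L, 16L))
  expect_true(all(sl$labels == 1L))

  tb <- generate_validation_geometry("tube", shape = c(64L, 32L, 32L),
                                     radius = 8)
  nlum <- sum(tb$labels == 2L)
  expect_lt(abs(nlum / (pi * 8^2 * 64) - 1), 0.05)
  # lumen opens on exactly the two z faces
  expect_true(any(tb$labels[1, , ] == 2L) && any(tb$labels[64, , ] == 2L))
  expect_false(any(tb$labels[, 1, ] == 2L) || any(tb$labels[, , 1] == 2L))

  sw <- generate_validation_geometry("sandwich", shape = c(30L, 8L, 8L),
                                     thickness = 10)
  # exactly t interstitial voxels between the lumen slabs in every column
  for (j in 1:8) for (k in 1:8) {
    col <- sw$labels[, j, k]
    expect_equal(sum(col == 1L), 10L)
    expect_equal(which(col == 1L), 11:20)
  }

  expect_error(generate_validation_geometry("tube", radius = 1),
               "unresolvable")
})
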