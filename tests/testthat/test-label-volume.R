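test_that("label volume validation enforces the declared label set", {
  a <- array(1L, c(4, 4, 4))
  expect_s3_class(label_volume(a, 13.2), "label_volume")
  a[1] <- 7L
  expect_error(label_volume(a, 13.2), "unknown label")
  expect_error(label_volume(array(1L, c(4, 4, 4)), -1), "voxel_pitch")
  expect_error(label_volume(array(1L, c(4, 4)), 13.2), "3D")
})

test_that("pleural shell must sit on the declared face", {
  a <- array(1L, c(6, 6, 6))
  a[1, , ] <- 4L
  expect_silent(validate_label_volume(label_volume(a, 10, "z-")))
  expect_error(label_volume(a, 10, "z+"), "does not touch")
  expect_error(label_volume(a, 10), "not declared")
  b <- array(1L, c(6, 6, 6))
  b[1, , ] <- 4L
  b[6, , ] <- 4L
  expect_error(label_volume(b, 10, "z-"))
})

test_that("write/read round-trips preserve labels and metadata", {
  vol <- std_voi()$volume
  for (ext in c(".nrrd", ".raw")) {
    f <- tempfile(fileext = ext)
    write_volume(vol, f)
    back <- read_volume(f)
    expect_identical(back$labels, vol$labels)
    expect_equal(back$voxel_pitch_um, vol$voxel_pitch_um)
    expect_identical(back$pleural_direction, vol$pleural_direction)
  }
  f <- tempfile(fileext = ".tif")
  write_volume(vol, f)
  expect_identical(read_volume(f)$labels, vol$labels)
})

test_that("reading rejects missing metadata and corrupt labels", {
  vol <- std_voi()$volume
  f <- tempfile(fileext = ".raw")
  write_volume(vol, f)
  side <- sub("\\.raw$", ".json", f)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  meta$voxel_pitch_um <- NULL
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  expect_error(read_volume(f), "voxel_pitch")
  expect_error(read_volume(tempfile(fileext = ".nrrd")), "no such file")
  # raw bytes with an out-of-range label fail validation on read
  f2 <- tempfile(fileext = ".raw")
  write_volume(vol, f2)
  raw <- readBin(f2, "raw", n = file.size(f2))
  raw[1] <- as.raw(9L)
  writeBin(raw, f2)
  expect_error(read_volume(f2), "unknown label")
})
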