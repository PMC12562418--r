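make_cube <- function(rows = 4, cols = 5, bands = 3, kind = "raw") {
  set.seed(1)
  hyper_cube(array(round(runif(rows * cols * bands) * 100, 3),
                   c(rows, cols, bands)),
             seq(400, 900, length.out = bands), kind = kind)
}

test_that("ENVI write/read round-trips bit-identically (float64) and closely (float32)", {
  cube <- make_cube()
  for (il in c("bil", "bsq")) {
    path <- withr::local_tempfile()
    write_envi(cube, path, interleave = il, data_type = 5)
    back <- read_envi(path)
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm)
    write_envi(cube, path, interleave = il, data_type = 4)
    expect_lt(max(abs(read_envi(path)$data - cube$data)), 1e-4)
  }
})

test_that("integer ENVI data types round-trip", {
  cube <- hyper_cube(array(sample(0:4000, 60), c(4, 5, 3)),
                     c(400, 500, 600), kind = "raw")
  path <- withr::local_tempfile()
  write_envi(cube, path, data_type = 12)   # uint16
  expect_identical(read_envi(path)$data, cube$data * 1.0)
})

test_that("interleave is honoured: BIL bytes reread as BSQ differ", {
  cube <- make_cube()
  path <- withr::local_tempfile()
  write_envi(cube, path, interleave = "bil")
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(sub("interleave = bil", "interleave = bsq", hdr),
             paste0(path, ".hdr"))
  misread <- read_envi(path)
  expect_false(isTRUE(all.equal(misread$data, cube$data)))
})

test_that("malformed headers fail with the offending field named", {
  cube <- make_cube()
  path <- withr::local_tempfile()
  write_envi(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(hdr[!grepl("^samples", hdr)], paste0(path, ".hdr"))
  expect_error(read_envi(path), "samples", class = "spectraseed_format_error")
  # wavelength count mismatch
  writeLines(sub("bands = 3", "bands = 4", hdr), paste0(path, ".hdr"))
  expect_error(read_envi(path), "wavelength", class = "spectraseed_format_error")
  # unsupported dtype
  writeLines(sub("data type = 4", "data type = 99", hdr), paste0(path, ".hdr"))
  expect_error(read_envi(path), "data type", class = "spectraseed_format_error")
})

test_that("calibration satisfies the white/dark/midpoint identities", {
  set.seed(2)
  white <- matrix(3000 + rnorm(20, sd = 5), 4)
  dark <- matrix(100 + rnorm(20), 4)
  as_cube <- function(m, bands = 3) {
    hyper_cube(array(rep(m, bands), c(4, 5, bands)), c(400, 500, 600), "raw")
  }
  expect_equal(max(abs(calibrate(as_cube(white), white, dark)$data - 1)), 0)
  expect_equal(max(abs(calibrate(as_cube(dark), white, dark)$data - 0)), 0)
  mid <- calibrate(as_cube((white + dark) / 2), white, dark)
  expect_lt(max(abs(mid$data - 0.5)), 1e-12)
})

test_that("calibration is invariant to common scaling of all three rasters", {
  set.seed(3)
  raw <- array(runif(60, 500, 2500), c(4, 5, 3))
  white <- matrix(3000 + rnorm(20, sd = 5), 4)
  dark <- matrix(100 + rnorm(20), 4)
  cube <- hyper_cube(raw, c(400, 500, 600), "raw")
  cube_s <- hyper_cube(raw * 7, c(400, 500, 600), "raw")
  a <- calibrate(cube, white, dark)
  b <- calibrate(cube_s, white * 7, dark * 7)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("degenerate references and clipping are surfaced, not silenced", {
  cube <- make_cube()
  white <- matrix(100, 4, 5); dark <- matrix(100, 4, 5)
  expect_error(calibrate(cube, white, dark), "non-positive",
               class = "spectraseed_calibration_error")
  # values above clip_max are clipped with a note counting them
  hot <- hyper_cube(array(5000, c(4, 5, 3)), c(400, 500, 600), "raw")
  expect_message(out <- calibrate(hot, matrix(3000, 4, 5), matrix(100, 4, 5)),
                 "clipped")
  expect_equal(max(out$data), 1.5)
})

test_that("multi-frame reference stacks are reduced to per-pixel means", {
  cube <- make_cube()
  white2 <- array(c(matrix(2900, 4, 5), matrix(3100, 4, 5)), c(4, 5, 2))
  out <- calibrate(cube, white2, matrix(100, 4, 5))
  ref <- calibrate(cube, matrix(3000, 4, 5), matrix(100, 4, 5))
  expect_equal(out$data, ref$data)
})

test_that("mean ROI spectra follow the exact pixel averages", {
  arr <- array(0, c(4, 6, 2))
  arr[, , 1] <- 0.4; arr[, , 2] <- 0.8
  cube <- hyper_cube(arr, c(500, 600), "reflectance")
  sp <- extract_mean_spectra(cube, list(roi(0, 2, 0, 3, seed_id = "a")))
  expect_equal(unname(spectra_matrix(sp)[1, ]), c(0.4, 0.8))
  # two-pixel ROI averages the two spectra
  arr2 <- array(0, c(1, 2, 2))
  arr2[1, 1, ] <- c(0.2, 0.4); arr2[1, 2, ] <- c(0.6, 0.8)
  cube2 <- hyper_cube(arr2, c(500, 600), "reflectance")
  sp2 <- extract_mean_spectra(cube2, list(roi(0, 1, 0, 2)))
  expect_equal(unname(spectra_matrix(sp2)[1, ]), c(0.4, 0.6))
  expect_error(extract_mean_spectra(cube2, list(roi(0, 1, 0, 5, seed_id = "bad"))),
               "bad", class = "spectraseed_format_error")
})

test_that("ROI sets round-trip through delimited text", {
  rois <- list(roi(0, 3, 1, 4, seed_id = "s1", label = 2L),
               roi(2, 5, 0, 2, seed_id = "s2", label = 7L))
  path <- withr::local_tempfile()
  write_rois(rois, path)
  expect_equal(read_rois(path), rois)
})

test_that("spectra tables round-trip through delimited text", {
  sp <- generate_spectra(tiny_cfg())
  path <- withr::local_tempfile()
  write_spectra(sp, path)
  back <- read_spectra(path)
  expect_equal(spectra_matrix(back), spectra_matrix(sp))
  expect_equal(spectra_labels(back), spectra_labels(sp))
})
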