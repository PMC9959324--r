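test_that("ENVI write/read round-trips a cube bit-identically", {
  cube <- toy_cube(7, 5, 6, calibrated = TRUE)
  path <- withr::local_tempfile(fileext = ".dat")
  write_envi_cube(cube, path)
  back <- read_envi_cube(path)
  expect_identical(back$values, cube$values)
  expect_identical(back$wavelengths, cube$wavelengths)
  expect_true(back$calibrated)
})

test_that("all three ENVI interleaves are normalized to (row, col, band)", {
  cube <- toy_cube(4, 3, 5)
  d <- dim(cube$values)
  for (il in c("bil", "bip")) {
    path <- withr::local_tempfile(fileext = ".raw")
    v <- switch(il,
                bil = aperm(cube$values, c(2, 3, 1)), # sample, band, line
                bip = aperm(cube$values, c(3, 2, 1))) # band, sample, line
    con <- file(path, "wb")
    writeBin(as.vector(v), con, size = 8, endian = "little")
    close(con)
    writeLines(c("ENVI",
                 sprintf("samples = %d", d[2]),
                 sprintf("lines = %d", d[1]),
                 sprintf("bands = %d", d[3]),
                 "data type = 5",
                 sprintf("interleave = %s", il),
                 sprintf("wavelength = { %s }",
                         paste(cube$wavelengths, collapse = ", "))),
               paste0(path, ".hdr"))
    back <- read_envi_cube(path)
    expect_equal(back$values, cube$values, info = il)
  }
})

test_that("header/raster inconsistencies raise structured errors", {
  cube <- toy_cube(4, 3, 5)
  path <- withr::local_tempfile(fileext = ".dat")
  write_envi_cube(cube, path)
  # header listing 4 wavelengths for a 5-band raster: count mismatch
  writeLines(c("ENVI", "samples = 3", "lines = 4", "bands = 5",
               "data type = 5", "interleave = bsq",
               "wavelength = { 400, 500, 600, 700 }"),
             paste0(path, ".hdr"))
  expect_error(read_envi_cube(path), class = "hsicnn_consistency_error")
  expect_error(read_envi_cube(file.path(tempdir(), "nope.dat")),
               class = "hsicnn_format_error")
})

test_that("a rendered phantom cube reads back with its full wavelength grid", {
  rec <- render_tissue_cube(phantom_config(seed = 5), "unhealthy", "c1",
                            seed = 5)
  expect_equal(dim(rec$cube$values), c(64, 64, 30))
  path <- withr::local_tempfile(fileext = ".dat")
  write_envi_cube(rec$cube, path)
  back <- read_envi_cube(path)
  expect_equal(length(back$wavelengths), 30)
  expect_identical(back$values, rec$cube$values)
})

test_that("calibration follows the flat-field formula with clipping", {
  wl <- wl_grid(4)
  white <- array(runif(60, 0.6, 1), c(5, 3, 4))
  dark <- array(runif(60, 0, 0.1), c(5, 3, 4))
  raw <- function(v) hsi_cube(v, wl)
  expect_equal(calibrate_reflectance(raw(white), white, dark)$values,
               array(1, c(5, 3, 4)))
  expect_equal(calibrate_reflectance(raw(dark), white, dark)$values,
               array(0, c(5, 3, 4)))
  mid <- calibrate_reflectance(raw((white + dark) / 2), white, dark)
  expect_equal(mid$values, array(0.5, c(5, 3, 4)))
  expect_true(mid$calibrated)
  expect_identical(mid$wavelengths, wl)
})

test_that("degenerate references are rejected, not divided by", {
  cube <- toy_cube(4, 3, 2)
  same <- array(0.5, c(4, 3, 2))
  expect_error(calibrate_reflectance(cube, same, same),
               class = "hsicnn_degenerate_reference_error")
})

test_that("identity calibration leaves a [0,1] cube unchanged", {
  cube <- toy_cube(5, 4, 3)
  cal <- calibrate_reflectance(cube, array(1, dim(cube$values)),
                               array(0, dim(cube$values)))
  expect_equal(cal$values, cube$values)
})

test_that("a per-line (rows x bands) white frame broadcasts like a full cube", {
  cube <- toy_cube(5, 4, 3)
  wline <- matrix(runif(15, 0.7, 1), 5, 3)
  wfull <- aperm(array(wline, c(5, 3, 4)), c(1, 3, 2))
  a <- calibrate_reflectance(cube, wline, 0)
  b <- calibrate_reflectance(cube, wfull, array(0, dim(cube$values)))
  expect_equal(a$values, b$values)
})

test_that("band-window cropping keeps inclusive endpoints in order", {
  cube <- hsi_cube(array(1, c(2, 2, 4)), c(400, 600, 800, 1000))
  crp <- crop_band_window(cube, 400, 800)
  expect_equal(crp$wavelengths, c(400, 600, 800))
  expect_equal(dim(crp$values)[3], 3)
  full <- crop_band_window(cube, 399, 1001)
  expect_identical(full$values, cube$values)
  expect_error(crop_band_window(cube, 405, 590),
               class = "hsicnn_empty_selection_error")
})

test_that("cropping a 408-band VNIR grid to 400-800 nm matches enumeration", {
  wl <- seq(400, 1000, length.out = 408)
  cube <- hsi_cube(array(0.5, c(2, 2, 408)), wl)
  crp <- crop_band_window(cube, 400, 800)
  # independent brute-force enumeration of the linear grid
  expected <- sum(vapply(wl, function(x) x >= 400 && x <= 800, logical(1)))
  expect_equal(dim(crp$values)[3], expected)
  expect_equal(crp$wavelengths, wl[wl >= 400 & wl <= 800])
})

test_that("nested band windows compose to the inner window", {
  cube <- toy_cube(3, 3, 20, wl = wl_grid(20, 400, 1000))
  inner <- crop_band_window(cube, 500, 700)
  nested <- crop_band_window(crop_band_window(cube, 450, 800), 500, 700)
  expect_identical(nested$values, inner$values)
  expect_identical(nested$wavelengths, inner$wavelengths)
})

test_that("multi-page TIFF export writes one page per band", {
  cube <- toy_cube(4, 4, 3, calibrated = TRUE)
  path <- withr::local_tempfile(fileext = ".tif")
  cube_to_tiff(cube, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 3)
  expect_equal(dim(pages[[1]]), c(4, 4))
})

test_that("float32 ENVI rasters are readable", {
  vals <- array(round(runif(24), 3), c(2, 3, 4))
  path <- withr::local_tempfile(fileext = ".raw")
  con <- file(path, "wb")
  writeBin(as.vector(aperm(vals, c(2, 1, 3))), con, size = 4,
           endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 3", "lines = 2", "bands = 4",
               "data type = 4", "interleave = bsq",
               "wavelength = { 400, 500, 600, 700 }"),
             paste0(path, ".hdr"))
  back <- read_envi_cube(path)
  expect_equal(back$values, vals, tolerance = 1e-6)
})
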