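make_cube <- function(value, dims = c(2, 2, 3), wl = c(900, 1000, 1100)) {
  hypercube(array(value, dims), wl, kind = "raw")
}

test_that("calibration reproduces the two-point reference formula", {
  raw <- make_cube(60)
  dark <- make_cube(20)
  white <- make_cube(100)
  expect_equal(calibrate(raw, dark, white)$data,
               array(0.5, c(2, 2, 3)))           # (60-20)/(100-20)
  expect_equal(calibrate(white, dark, white)$data, array(1, c(2, 2, 3)))
  expect_equal(calibrate(dark, dark, white)$data, array(0, c(2, 2, 3)))
})

test_that("calibration is affine-invariant in the reference span", {
  set.seed(1)
  dark <- hypercube(array(rnorm(12, 100, 5), c(2, 2, 3)), c(900, 1000, 1100))
  white <- hypercube(array(rnorm(12, 4000, 20), c(2, 2, 3)), c(900, 1000, 1100))
  for (t in c(-0.5, 0, 0.3, 1, 2)) {
    raw <- hypercube(dark$data + t * (white$data - dark$data),
                     dark$wavelengths)
    out <- calibrate(raw, dark, white)
    expect_equal(out$data, array(t, c(2, 2, 3)), tolerance = 1e-12)
  }
})

test_that("reflectance stays in [0, 1] when raw lies between the references", {
  set.seed(2)
  wl <- c(900, 1000, 1100)
  dark <- hypercube(array(runif(12, 90, 110), c(2, 2, 3)), wl)
  white <- hypercube(array(runif(12, 3900, 4100), c(2, 2, 3)), wl)
  mix <- array(runif(12), c(2, 2, 3))
  raw <- hypercube(dark$data + mix * (white$data - dark$data), wl)
  rho <- calibrate(raw, dark, white)$data
  expect_true(all(rho >= 0 & rho <= 1))
})

test_that("single-row scanline references broadcast across image rows", {
  wl <- c(900, 1000)
  raw <- hypercube(array(60, c(3, 2, 2)), wl)
  dark <- hypercube(array(20, c(1, 2, 2)), wl)
  white <- hypercube(array(100, c(1, 2, 2)), wl)
  expect_equal(calibrate(raw, dark, white)$data, array(0.5, c(3, 2, 2)))
})

test_that("dimension mismatches and degenerate denominators are caught", {
  raw <- make_cube(60)
  expect_error(calibrate(raw, make_cube(20, c(3, 2, 3)), make_cube(100)),
               "incompatible")
  expect_error(
    calibrate(raw, make_cube(20), make_cube(100, wl = c(901, 1000, 1100))),
    "wavelength"
  )
  # white == dark: every entry flagged
  expect_warning(
    out <- calibrate(raw, make_cube(20), make_cube(20)),
    "epsilon"
  )
  expect_true(all(is.na(out$data)))
  expect_equal(attr(out, "n_flagged"), 12L)
  expect_error(
    calibrate(raw, make_cube(20), make_cube(20), on_bad_pixel = "error"),
    "epsilon"
  )
})

test_that("spectral cropping keeps exactly the closed-interval bands", {
  spec <- clean_spec()
  scene <- generate_scene(spec)
  cube <- scene$raw
  wl <- cube$wavelengths

  full <- crop_spectral_range(cube, 874.41, 1733.91)
  expect_equal(n_bands(full), 256L)

  cropped <- crop_spectral_range(cube, 975, 1646)
  expect_equal(n_bands(cropped), sum(wl >= 975 & wl <= 1646))
  expect_true(all(cropped$wavelengths >= 975 & cropped$wavelengths <= 1646))

  expect_error(crop_spectral_range(cube, 2000, 3000), "no bands")
  expect_error(crop_spectral_range(cube, 1100, 1000), "smaller")
})

test_that("ENVI write/read round-trips cubes and wavelengths", {
  set.seed(3)
  cube <- hypercube(array(rnorm(2 * 3 * 4), c(2, 3, 4)),
                    c(900.1234, 1000.5, 1100.25, 1200), kind = "reflectance")
  p <- withr::local_tempfile(fileext = ".img")
  write_cube(cube, p)
  once <- read_cube(p)
  write_cube(once, p)
  twice <- read_cube(p)
  # float32 quantisation happens once; after that the file is a fixed point
  expect_identical(once$data, twice$data)
  expect_equal(once$data, cube$data, tolerance = 1e-6)
  expect_lt(max(abs(once$wavelengths - cube$wavelengths)), 1e-4)
  expect_identical(once$kind, "reflectance")

  # minimal 1 x 1 x 2 cube
  tiny <- hypercube(array(c(0.25, 0.5), c(1, 1, 2)), c(900, 1000))
  p2 <- withr::local_tempfile(fileext = ".img")
  write_cube(tiny, p2)
  expect_equal(read_cube(p2)$data, tiny$data)
})

test_that("malformed ENVI headers fail with the offending field named", {
  cube <- hypercube(array(0.5, c(2, 2, 2)), c(900, 1000))
  p <- withr::local_tempfile(fileext = ".img")
  write_cube(cube, p)
  hdr <- paste0(tools::file_path_sans_ext(p), ".hdr")

  no_wl <- grep("wavelength =", readLines(hdr), invert = TRUE, value = TRUE,
                fixed = TRUE)
  writeLines(no_wl, hdr)
  expect_error(read_cube(p), "wavelength")

  write_cube(cube, p)
  bad <- sub("interleave = bsq", "interleave = weird", readLines(hdr))
  writeLines(bad, hdr)
  expect_error(read_cube(p), "interleave")
})

test_that("band-nearest selection uses the lower wavelength on ties", {
  cube <- hypercube(array(seq_len(8), c(2, 1, 4)),
                    c(1000, 1100, 1200, 1300))
  on_grid <- select_segmentation_band(cube, 1200)
  expect_equal(attr(on_grid, "band_index"), 3L)
  midway <- select_segmentation_band(cube, 1150)   # tie: 1100 vs 1200
  expect_equal(attr(midway, "wavelength"), 1100)

  # default target resolved by exhaustive nearest search
  spec <- tiny_spec()
  scene <- generate_scene(spec)
  got <- select_segmentation_band(scene$raw)
  wl <- scene$raw$wavelengths
  expect_equal(attr(got, "band_index"), which.min(abs(wl - 1139.26)))
})
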