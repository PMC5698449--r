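test_that("base spectrum has the expected peak and valleys", {
  spec <- tiny_spec()
  bs <- base_spectrum(spec)
  wl <- bs$wavelength
  r <- bs$reflectance

  expect_true(all(r > 0 & r < 1))
  # reflectance peak near 1122.81 nm
  win <- wl >= 1050 & wl <= 1180
  peak_wl <- wl[win][which.max(r[win])]
  expect_lt(abs(peak_wl - 1122.81), 15)
  # valleys near 1200.19 and 1483.46 nm, located by exhaustive scan
  expect_lt(abs(oracle_local_min(wl, r, 1150, 1250) - 1200.19), 15)
  expect_lt(abs(oracle_local_min(wl, r, 1400, 1560) - 1483.46), 15)
})

test_that("base spectrum is deterministic and flattens with zero amplitudes", {
  s1 <- tiny_spec()
  s2 <- scene_spec(n_seeds_per_class = c(5, 1), rng_seed = 999)
  expect_identical(base_spectrum(s1)$reflectance,
                   base_spectrum(s2)$reflectance)

  flat <- scene_spec(feature_amplitudes = c(0, 0, 0))
  expect_equal(diff(range(base_spectrum(flat)$reflectance)), 0)
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(n_bands = 1), "n_bands")
  expect_error(scene_spec(wl_start = 1700, wl_end = 900), "wl_start")
  expect_error(scene_spec(scatter_sd = -0.1), "scatter_sd")
  expect_error(scene_spec(class_offset = 0), "class_offset")
  expect_error(scene_spec(n_seeds_per_class = c(-1, 3)), "n_seeds_per_class")
})

test_that("generated scenes have the requested seeds, disjoint and countable", {
  scene <- generate_scene(tiny_spec())
  expect_equal(nrow(scene$truth), 6L)
  expect_equal(sum(scene$truth$class == 1L), 3L)
  expect_equal(sum(scene$truth$class == 2L), 3L)
  # every planted id appears and each pixel carries one id by construction
  expect_setequal(unique(scene$labels[scene$labels > 0]), 1:6)
  # reference frames are single-scanline cubes on the same grid
  expect_equal(dim(scene$dark$data)[1], 1L)
  expect_identical(scene$dark$wavelengths, scene$raw$wavelengths)
})

test_that("scene generation is deterministic in the rng seed", {
  a <- generate_scene(tiny_spec())
  b <- generate_scene(tiny_spec())
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$labels, b$labels)

  c <- generate_scene(scene_spec(n_seeds_per_class = c(3, 3), rng_seed = 12))
  expect_false(identical(a$raw$data, c$raw$data))
})

test_that("too-small images raise a placement error", {
  expect_error(
    generate_scene(scene_spec(n_seeds_per_class = c(30, 30),
                              image_height = 40, image_width = 40)),
    "placement"
  )
})

test_that("noiseless scenes round-trip the base spectrum exactly", {
  spec <- clean_spec()
  scene <- generate_scene(spec)
  cal <- calibrate(scene$raw, scene$dark, scene$white)
  base <- base_spectrum(spec)$reflectance
  for (id in scene$truth$seed_id) {
    m <- mean_spectrum(cal, scene$labels == id)
    expect_lt(max(abs(m - base)), 1e-10)
  }
})

test_that("planted mutant seeds are larger in area, as parameterised", {
  scene <- generate_scene(scene_spec(n_seeds_per_class = c(200, 200),
                                     rng_seed = 21))
  mu <- tapply(scene$truth$area, scene$truth$class, mean)
  expect_gt(mu[["2"]], mu[["1"]])
  len <- tapply(scene$truth$length, scene$truth$class, mean)
  expect_gt(len[["2"]], len[["1"]])
})

test_that("direct spectral datasets have the declared structure", {
  spec <- scene_spec(n_seeds_per_class = c(330, 330), rng_seed = 3)
  ds <- generate_spectral_dataset(spec, 330)
  expect_s3_class(ds, "spectral_dataset")
  expect_equal(nrow(ds), 660L)
  expect_equal(sum(ds$class == 1L), 330L)
  expect_equal(ncol(spectral_matrix(ds)), 256L)

  # determinism: same spec and seed give bit-identical matrices
  ds2 <- generate_spectral_dataset(spec, 330)
  expect_identical(spectral_matrix(ds), spectral_matrix(ds2))
})

test_that("zero noise and scatter collapse each class to one spectrum", {
  spec <- scene_spec(noise_sd = 0, scatter_sd = 0, rng_seed = 8)
  ds <- generate_spectral_dataset(spec, 5)
  X <- spectral_matrix(ds)
  for (cl in 1:2) {
    rows <- X[ds$class == cl, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(col) diff(range(col)))), 0)
  }
  # and the two classes differ exactly by the offset profile
  expect_equal(X[ds$class == 2L, ][1, ] / X[ds$class == 1L, ][1, ],
               rep(spec$class_offset, 256),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("planted class reflectance ratio matches class_offset at scale", {
  spec <- scene_spec(n_seeds_per_class = c(250, 250), rng_seed = 17)
  ds <- generate_spectral_dataset(spec, 250)
  X <- spectral_matrix(ds)
  ratio <- mean(X[ds$class == 2L, ]) / mean(X[ds$class == 1L, ])
  # Monte-Carlo error of the mean scatter is ~ scatter_sd * sqrt(2/250)
  expect_lt(abs(ratio - spec$class_offset), 4 * spec$scatter_sd * sqrt(2 / 250))
})

test_that("truth tables serialise to CSV", {
  scene <- generate_scene(tiny_spec())
  p <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(scene, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), 6L)
  expect_named(back, c("seed_id", "class", "area", "perimeter", "length",
                       "width", "centroid_row", "centroid_col"))
})
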