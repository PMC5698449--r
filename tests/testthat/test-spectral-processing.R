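test_that("ROI mean spectra average exactly", {
  wl <- c(900, 1000, 1100)
  d <- array(0, c(2, 2, 3))
  s1 <- c(0.2, 0.4, 0.6)
  s2 <- c(0.4, 0.2, 0.8)
  d[1, 1, ] <- s1
  d[2, 1, ] <- s2
  cube <- hypercube(d, wl, "reflectance")

  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube, one), s1)
  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube, two), (s1 + s2) / 2)
  expect_error(mean_spectrum(cube, matrix(FALSE, 2, 2)), "empty")
})

test_that("noiseless seeds return base x offset x scatter to 1e-10", {
  spec <- scene_spec(n_seeds_per_class = c(2, 2), noise_sd = 0,
                     rng_seed = 4)  # scatter still on
  scene <- generate_scene(spec)
  cal <- calibrate(scene$raw, scene$dark, scene$white)
  base <- base_spectrum(spec)$reflectance
  offset <- ifelse(scene$truth$class == 2L, spec$class_offset, 1)
  for (i in scene$truth$seed_id) {
    m <- mean_spectrum(cal, scene$labels == i)
    planted <- base * offset[i] * scene$truth$scatter[i]
    expect_lt(max(abs(m - planted)), 1e-10)
  }
})

test_that("wavelet denoising leaves constants untouched", {
  x <- rep(0.37, 199)
  expect_lt(max(abs(wavelet_denoise(x) - x)), 1e-8)
})

test_that("wavelet decomposition reconstructs perfectly without thresholding", {
  withr::with_seed(9, {
    for (n in c(64, 199, 256)) {
      x <- rnorm(n)
      expect_lt(max(abs(wavelet_denoise(x, threshold = "none") - x)), 1e-10)
    }
  })
})

test_that("denoising shrinks white noise and improves noisy spectra", {
  base <- base_spectrum(tiny_spec())$reflectance[seq_len(199)]

  withr::with_seed(31, {
    # pure white noise: variance must strictly decrease
    noise <- rnorm(199)
    expect_lt(var(wavelet_denoise(noise)), var(noise))

    # SNR 20 dB around the smooth base: MSE to the clean curve drops
    noise_sd <- sd(base) / 10  # noise power 20 dB below signal power
    improved <- 0L
    reps <- 100L
    for (i in seq_len(reps)) {
      noisy <- base + rnorm(199, 0, noise_sd)
      den <- wavelet_denoise(noisy)
      if (mean((den - base)^2) < mean((noisy - base)^2)) {
        improved <- improved + 1L
      }
    }
    expect_gt(improved / reps, 0.9)
  })
})

test_that("denoising barely changes an already-smooth spectrum", {
  base <- base_spectrum(tiny_spec())$reflectance
  den <- wavelet_denoise(base)
  rms_change <- sqrt(mean((den - base)^2)) / sqrt(mean(base^2))
  expect_lt(rms_change, 0.01)
})

test_that("too-short spectra are rejected with the minimum length named", {
  expect_error(wavelet_denoise(rnorm(10)), "15")
})

test_that("build_dataset assembles rows in object order with given labels", {
  spec <- clean_spec()
  scene <- generate_scene(spec)
  cal <- calibrate(scene$raw, scene$dark, scene$white)
  seg <- segment_seeds(select_segmentation_band(cal))
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  ds <- build_dataset(cal, seg, labels)
  expect_equal(nrow(ds), 6L)
  expect_equal(ds$class, labels)
  expect_equal(ncol(spectral_matrix(ds)), sum(cal$wavelengths >= 975 &
                                                cal$wavelengths <= 1646))

  # with denoising off, rows equal the raw ROI means
  ds_raw <- build_dataset(cal, seg, labels, denoise = FALSE)
  cropped <- crop_spectral_range(cal, 975, 1646)
  for (i in seq_len(6)) {
    m <- mean_spectrum(cropped, seed_mask(seg, seg$objects$object_id[i]))
    expect_equal(unname(spectral_matrix(ds_raw)[i, ]), m)
  }

  expect_error(build_dataset(cal, seg, c(1L, 2L)), "labels")
})

test_that("build_dataset is permutation-equivariant in the seeds", {
  spec <- clean_spec()
  scene <- generate_scene(spec)
  cal <- calibrate(scene$raw, scene$dark, scene$white)
  seg <- segment_seeds(select_segmentation_band(cal))
  labels <- c(1L, 2L, 1L, 2L, 1L, 2L)
  ds <- build_dataset(cal, seg, labels, denoise = FALSE)

  # relabel objects in reversed scan order and rebuild
  perm <- 6:1
  seg2 <- seg
  seg2$labels[seg$labels > 0] <- perm[seg$labels[seg$labels > 0]]
  seg2$objects <- seg$objects
  seg2$objects$object_id <- perm[seg$objects$object_id]
  seg2$objects <- seg2$objects[order(seg2$objects$object_id), ]
  ds2 <- build_dataset(cal, seg2, labels[order(perm)], denoise = FALSE)
  expect_equal(spectral_matrix(ds2), spectral_matrix(ds)[order(perm), ],
               ignore_attr = TRUE)
})

test_that("datasets round-trip through CSV + JSON sidecar", {
  ds <- small_dataset(6)
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectral_dataset(ds, p)
  back <- read_spectral_dataset(p)
  expect_equal(spectral_matrix(back), spectral_matrix(ds),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$class, ds$class)
  expect_equal(wavelengths(back), wavelengths(ds), tolerance = 1e-4)
})
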