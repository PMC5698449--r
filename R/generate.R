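#' Generate a synthetic hyperspectral seed scene
#'
#' Simulates one push-broom acquisition: non-overlapping elliptical seeds
#' (rotated uniformly in `[0, pi)`, axes drawn from the per-class truncated
#' normals in `spec$seed_shape`) on a dark background, plus single-row dark
#' and white reference frames. The raw cube is built as
#' `raw = dark + (white - dark) * reflectance + noise`, so calibrating with
#' the returned references recovers the planted reflectances exactly when
#' noise and scatter are zero.
#'
#' Seeds are placed on a shuffled jittered grid, which guarantees
#' disjointness; if the requested image is too small to host all seeds a
#' placement error is raised.
#'
#' @param spec a [scene_spec()].
#' @return A list of class `seed_scene` with elements
#'   \describe{
#'     \item{raw}{raw-intensity [hypercube()]}
#'     \item{dark, white}{single-row reference cubes}
#'     \item{truth}{tibble of planted seeds: `seed_id`, `class`, analytic
#'       `area`, `perimeter`, `length`, `width`, `centroid_row`,
#'       `centroid_col`, `theta`, `scatter`}
#'     \item{labels}{integer raster of planted seed ids (0 = background)}
#'   }
#' @examples
#' scene <- generate_scene(scene_spec(n_seeds_per_class = c(2, 2)))
#' nrow(scene$truth)
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_rng(spec$rng_seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  wl <- wavelength_grid(spec)
  n_wt <- spec$n_seeds_per_class[1L]
  n_mu <- spec$n_seeds_per_class[2L]
  n <- n_wt + n_mu
  if (n < 1L) abort("the scene must contain at least one seed.")
  cls <- sample(rep(c(1L, 2L), c(n_wt, n_mu)))

  shp <- spec$seed_shape
  row_of <- match(cls, shp$class)
  len <- rtruncnorm3(n, shp$length_mean[row_of], shp$length_sd[row_of])
  wid <- rtruncnorm3(n, shp$width_mean[row_of], shp$width_sd[row_of])
  wid <- pmin(wid, len)
  theta <- runif(n, 0, pi)
  scatter <- pmax(rnorm(n, 1, spec$scatter_sd), 0.5)

  # jittered-grid layout: cells large enough for the longest rotated seed
  cell <- ceiling(max(len)) + 4L
  if (is.null(spec$image_height) || is.null(spec$image_width)) {
    gc <- ceiling(sqrt(n))
    gr <- ceiling(n / gc)
    nr <- gr * cell
    nc <- gc * cell
  } else {
    nr <- spec$image_height
    nc <- spec$image_width
    gr <- nr %/% cell
    gc <- nc %/% cell
    if (gr * gc < n) {
      abort(sprintf(
        "placement error: %dx%d px holds at most %d seeds of this size, %d requested.",
        nr, nc, gr * gc, n
      ))
    }
  }
  cells <- sample(gr * gc, n)
  cell_r <- (cells - 1L) %/% gc
  cell_c <- (cells - 1L) %% gc
  # seed bounding half-extents after rotation
  ex <- sqrt((len / 2 * cos(theta))^2 + (wid / 2 * sin(theta))^2)
  ey <- sqrt((len / 2 * sin(theta))^2 + (wid / 2 * cos(theta))^2)
  jit_r <- pmax(cell / 2 - ey - 1.5, 0)
  jit_c <- pmax(cell / 2 - ex - 1.5, 0)
  cy <- cell_r * cell + cell / 2 + runif(n, -1, 1) * jit_r
  cx <- cell_c * cell + cell / 2 + runif(n, -1, 1) * jit_c

  labels <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    px <- ellipse_pixels(cy[i], cx[i], len[i] / 2, wid[i] / 2, theta[i], nr, nc)
    labels[px] <- i
  }

  base <- base_spectrum_vec(spec, wl)
  offset <- class_offset_profile(spec, wl)
  nb <- length(wl)
  npix <- nr * nc
  refl <- matrix(spec$background_reflectance, npix, nb)
  for (i in seq_len(n)) {
    px <- which(labels == i)
    s <- base * scatter[i]
    if (cls[i] == 2L) s <- s * offset
    refl[px, ] <- tcrossprod(rep(1, length(px)), s)
  }
  nprof <- noise_profile(spec, wl)
  if (spec$noise_sd > 0) {
    for (b in seq_len(nb)) {
      refl[, b] <- refl[, b] + rnorm(npix, 0, nprof[b])
    }
  }

  # single-row reference frames (scanline convention), mild fixed-pattern noise
  dark_f <- matrix(spec$dark_level, nc, nb) +
    matrix(rnorm(nc * nb, 0, spec$dark_level * 0.005), nc, nb)
  white_f <- matrix(spec$white_level, nc, nb) +
    matrix(rnorm(nc * nb, 0, spec$white_level * 0.002), nc, nb)

  col_idx <- rep(seq_len(nc), each = nr)
  raw <- matrix(0, npix, nb)
  for (b in seq_len(nb)) {
    d <- dark_f[, b][col_idx]
    span <- (white_f[, b] - dark_f[, b])[col_idx]
    raw[, b] <- d + span * refl[, b]
  }

  semi_a <- len / 2
  semi_b <- wid / 2
  truth <- tibble(
    seed_id = seq_len(n),
    class = cls,
    area = pi * semi_a * semi_b,
    perimeter = ellipse_perimeter(semi_a, semi_b),
    length = len,
    width = wid,
    centroid_row = cy,
    centroid_col = cx,
    theta = theta,
    scatter = scatter
  )

  dim(raw) <- c(nr, nc, nb)  # same element order: no copy
  structure(
    list(
      raw = hypercube(raw, wl, kind = "raw"),
      # frames are cols x bands; as arrays they become 1 x cols x bands
      dark = hypercube(array(dark_f, c(1L, nc, nb)), wl, kind = "raw"),
      white = hypercube(array(white_f, c(1L, nc, nb)), wl, kind = "raw"),
      truth = truth,
      labels = labels,
      spec = spec
    ),
    class = "seed_scene"
  )
}

#' @export
print.seed_scene <- function(x, ...) {
  d <- dim(x$raw$data)
  cat(sprintf(
    "<seed_scene> %d seeds (%d WT / %d mutant) on %d x %d px, %d bands\n",
    nrow(x$truth), sum(x$truth$class == 1L), sum(x$truth$class == 2L),
    d[1L], d[2L], d[3L]
  ))
  invisible(x)
}

# Linear pixel indices of a filled rotated ellipse, clipped to the image.
ellipse_pixels <- function(cy, cx, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cy - a - 1))
  r1 <- min(nr, ceiling(cy + a + 1))
  c0 <- max(1L, floor(cx - a - 1))
  c1 <- min(nc, ceiling(cx + a + 1))
  rr <- r0:r1
  cc <- c0:c1
  dy <- rep(rr - cy, times = length(cc))
  dx <- rep(cc - cx, each = length(rr))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  rows <- rep(rr, times = length(cc))[inside]
  cols <- rep(cc, each = length(rr))[inside]
  (cols - 1L) * nr + rows
}

# Ramanujan's approximation for the ellipse circumference.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Generate labelled spectra directly (bypassing imaging)
#'
#' Emits a [spectral_dataset()] with the same statistical structure a full
#' generate/calibrate/segment/extract run would produce: each row is
#' `base x class-offset x per-seed scatter + noise`, where the additive
#' noise SD is the per-pixel `noise_sd` attenuated by averaging over a
#' typical seed's pixels. Much faster than imaging when only the
#' classifier stages are under study.
#'
#' @param spec a [scene_spec()]; `rng_seed` drives all randomness.
#' @param n_per_class seeds per class (the imaging studies emulated here
#'   use 330 per class, i.e. 660 seeds per variety).
#' @param pixel_averaging number of pixels a seed's mean spectrum averages
#'   over; defaults to the mean planted seed area.
#' @return A [spectral_dataset()] with `2 * n_per_class` rows.
#' @export
generate_spectral_dataset <- function(spec, n_per_class,
                                      pixel_averaging = NULL) {
  validate_scene_spec(spec)
  if (n_per_class < 1L) abort("`n_per_class` must be >= 1.")
  if (is.null(pixel_averaging)) {
    shp <- spec$seed_shape
    pixel_averaging <- mean(pi * (shp$length_mean / 2) * (shp$width_mean / 2))
  }
  wl <- wavelength_grid(spec)
  base <- base_spectrum_vec(spec, wl)
  offset <- class_offset_profile(spec, wl)
  nprof <- noise_profile(spec, wl) / sqrt(pixel_averaging)
  n <- 2L * n_per_class
  cls <- rep(c(1L, 2L), each = n_per_class)
  with_rng(spec$rng_seed, {
    scatter <- pmax(rnorm(n, 1, spec$scatter_sd), 0.5)
    X <- matrix(0, n, length(wl))
    for (i in seq_len(n)) {
      s <- base * scatter[i]
      if (cls[i] == 2L) s <- s * offset
      X[i, ] <- s
    }
    if (spec$noise_sd > 0) {
      X <- X + matrix(rnorm(n * length(wl)), n, length(wl)) *
        matrix(nprof, n, length(wl), byrow = TRUE)
    }
    spectral_dataset(X, cls, wl, variety = spec$variety)
  })
}

#' Write the planted-seed truth table as CSV
#'
#' @param scene a `seed_scene` from [generate_scene()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(scene, path) {
  utils::write.csv(
    scene$truth[, c("seed_id", "class", "area", "perimeter", "length",
                    "width", "centroid_row", "centroid_col")],
    path, row.names = FALSE
  )
  invisible(path)
}
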