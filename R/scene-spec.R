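#' Shape statistics for simulated rice seeds
#'
#' Per-class means and standard deviations (in pixels) of the four shape
#' features used throughout the package: area, perimeter, and the major
#' (length) / minor (width) axis of the pixel blob. The defaults reproduce
#' the morphometry reported for two rice varieties and their TGW6-knockout
#' mutants: mutants have larger area, perimeter and length but essentially
#' unchanged width. Class 1 is wild type, class 2 the mutant.
#'
#' @param variety `"huaidao-1"` or `"nanjing46"`.
#' @return A tibble with one row per class and `*_mean` / `*_sd` columns for
#'   the four features.
#' @export
seed_shape_defaults <- function(variety = c("huaidao-1", "nanjing46")) {
  variety <- match.arg(variety)
  if (variety == "huaidao-1") {
    tibble(
      class = c(1L, 2L),
      area_mean = c(61.31, 65.28), area_sd = c(6.32, 6.29),
      perimeter_mean = c(29.43, 30.95), perimeter_sd = c(1.53, 1.65),
      length_mean = c(11.20, 11.76), length_sd = c(0.61, 0.62),
      width_mean = c(5.65, 5.73), width_sd = c(0.44, 0.37)
    )
  } else {
    tibble(
      class = c(1L, 2L),
      area_mean = c(54.73, 55.88), area_sd = c(5.90, 7.99),
      perimeter_mean = c(27.96, 28.18), perimeter_sd = c(1.62, 2.47),
      length_mean = c(10.34, 10.85), length_sd = c(0.61, 0.72),
      width_mean = c(5.33, 5.36), width_sd = c(0.44, 0.41)
    )
  }
}

#' Specify a synthetic hyperspectral seed scene
#'
#' A `scene_spec` fixes every parameter of the synthetic-image generator:
#' the wavelength grid, how many seeds of each class to place, per-class
#' seed shape statistics, the spectral contrast between classes, and the
#' noise structure. The defaults emulate a push-broom NIR line scanner
#' (256 uniform channels over 874.41-1733.91 nm, noisier outside
#' 975-1646 nm) imaging rice seeds whose mutant class reflects uniformly
#' ~2% more light than wild type and is slightly larger.
#'
#' `class_offset` acts multiplicatively on the mutant reflectance, across
#' the whole spectrum by default; `offset_windows` restricts it to given
#' wavelength intervals (useful for planting known discriminative bands).
#' `scatter_sd` is the SD of a per-seed multiplicative scatter factor (the
#' dominant seed-to-seed variability); `noise_sd` the SD of additive
#' per-pixel reflectance noise, inflated by `edge_noise_gain` outside
#' 975-1646 nm.
#'
#' @param image_height,image_width scene size in pixels, or `NULL` to size
#'   the image automatically from the seed count.
#' @param n_bands number of spectral channels (>= 2).
#' @param wl_start,wl_end wavelength-grid endpoints in nm.
#' @param n_seeds_per_class length-2 counts `c(wt, mutant)`.
#' @param seed_shape per-class shape statistics as from
#'   [seed_shape_defaults()].
#' @param class_offset mutant reflectance multiplier (> 0).
#' @param offset_windows optional list of `c(lo, hi)` nm intervals outside
#'   which `class_offset` does not act.
#' @param scatter_sd,noise_sd,edge_noise_gain noise parameters (>= 0).
#' @param feature_amplitudes named reflectance amplitudes of the base
#'   spectrum's Gaussian features (see [base_spectrum()]).
#' @param background_reflectance constant background level in (0, 1).
#' @param dark_level,white_level reference frame intensity counts.
#' @param variety label recorded in generated truth tables.
#' @param rng_seed integer seed driving all randomness of the generator.
#' @return An object of class `scene_spec` (a named list).
#' @examples
#' spec <- scene_spec(n_seeds_per_class = c(3, 3), rng_seed = 7)
#' spec$n_bands
#' @export
scene_spec <- function(image_height = NULL,
                       image_width = NULL,
                       n_bands = 256,
                       wl_start = 874.41,
                       wl_end = 1733.91,
                       n_seeds_per_class = c(wt = 3, mutant = 3),
                       seed_shape = seed_shape_defaults("huaidao-1"),
                       class_offset = 1.02,
                       offset_windows = NULL,
                       scatter_sd = 0.006,
                       noise_sd = 0.01,
                       edge_noise_gain = 4,
                       feature_amplitudes = c(peak_1122 = 0.12,
                                              valley_1200 = -0.09,
                                              valley_1483 = -0.13),
                       background_reflectance = 0.08,
                       dark_level = 100,
                       white_level = 4000,
                       variety = "huaidao-1",
                       rng_seed = 1L) {
  spec <- list(
    image_height = image_height, image_width = image_width,
    n_bands = as.integer(n_bands), wl_start = wl_start, wl_end = wl_end,
    n_seeds_per_class = as.integer(n_seeds_per_class),
    seed_shape = seed_shape,
    class_offset = class_offset, offset_windows = offset_windows,
    scatter_sd = scatter_sd, noise_sd = noise_sd,
    edge_noise_gain = edge_noise_gain,
    feature_amplitudes = feature_amplitudes,
    background_reflectance = background_reflectance,
    dark_level = dark_level, white_level = white_level,
    variety = variety,
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  if (spec$n_bands < 2L) abort("invalid scene_spec: `n_bands` must be >= 2.")
  if (!(spec$wl_start < spec$wl_end)) {
    abort("invalid scene_spec: `wl_start` must be smaller than `wl_end`.")
  }
  if (length(spec$n_seeds_per_class) != 2L ||
      any(spec$n_seeds_per_class < 0L)) {
    abort("invalid scene_spec: `n_seeds_per_class` must be 2 non-negative counts.")
  }
  for (nm in c("scatter_sd", "noise_sd", "edge_noise_gain")) {
    if (spec[[nm]] < 0) abort(sprintf("invalid scene_spec: `%s` must be >= 0.", nm))
  }
  if (spec$class_offset <= 0) {
    abort("invalid scene_spec: `class_offset` must be > 0.")
  }
  if (spec$background_reflectance <= 0 || spec$background_reflectance >= 1) {
    abort("invalid scene_spec: `background_reflectance` must be in (0, 1).")
  }
  needed <- c("class", "length_mean", "length_sd", "width_mean", "width_sd")
  if (!all(needed %in% names(spec$seed_shape))) {
    abort("invalid scene_spec: `seed_shape` lacks required columns.")
  }
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d WT + %d mutant seeds, %d bands %.2f-%.2f nm\n",
    x$n_seeds_per_class[1L], x$n_seeds_per_class[2L],
    x$n_bands, x$wl_start, x$wl_end
  ))
  cat(sprintf(
    "  class_offset %.4g, scatter_sd %.4g, noise_sd %.4g (edge gain %.3g)\n",
    x$class_offset, x$scatter_sd, x$noise_sd, x$edge_noise_gain
  ))
  invisible(x)
}

#' Wavelength grid of a scene specification
#' @param spec a [scene_spec()].
#' @return numeric vector of `n_bands` uniformly spaced wavelengths in nm.
#' @export
wavelength_grid <- function(spec) {
  seq(spec$wl_start, spec$wl_end, length.out = spec$n_bands)
}

#' Deterministic base reflectance spectrum of a seed
#'
#' A flat baseline (0.45) plus three Gaussian features at fixed positions:
#' a reflectance peak near 1122.81 nm and valleys near 1200.19 and
#' 1483.46 nm, matching the peak/valley structure typical of unshelled rice
#' seeds in the NIR (C-H second-overtone and N-H first-overtone bands).
#' The curve is the class-1 (wild type) seed spectrum before per-seed
#' scatter and noise; it does not depend on `rng_seed`.
#'
#' @param spec a [scene_spec()].
#' @return A tibble with columns `wavelength` (nm) and `reflectance`.
#' @export
base_spectrum <- function(spec) {
  validate_scene_spec(spec)
  wl <- wavelength_grid(spec)
  tibble(wavelength = wl, reflectance = base_spectrum_vec(spec, wl))
}

base_spectrum_vec <- function(spec, wl = wavelength_grid(spec)) {
  amp <- spec$feature_amplitudes
  centres <- c(1122.81, 1200.19, 1483.46)
  widths <- c(30, 22, 45)
  refl <- rep(0.45, length(wl))
  for (i in seq_along(centres)) {
    refl <- refl + amp[[i]] * exp(-((wl - centres[i])^2) / (2 * widths[i]^2))
  }
  pmin(pmax(refl, 1e-3), 1 - 1e-3)
}

# Per-band multiplier applied to class-2 (mutant) reflectance.
class_offset_profile <- function(spec, wl = wavelength_grid(spec)) {
  gain <- rep(1, length(wl))
  if (is.null(spec$offset_windows)) {
    gain[] <- spec$class_offset
  } else {
    inside <- Reduce(`|`, lapply(spec$offset_windows, function(w) {
      wl >= w[1L] & wl <= w[2L]
    }))
    gain[inside] <- spec$class_offset
  }
  gain
}

# Band indices the class offset acts on (the planted discriminative bands).
planted_bands <- function(spec, wl = wavelength_grid(spec)) {
  which(class_offset_profile(spec, wl) != 1)
}

# Additive noise SD per band: inflated outside the clean 975-1646 nm range.
noise_profile <- function(spec, wl = wavelength_grid(spec)) {
  sd <- rep(spec$noise_sd, length(wl))
  edge <- wl < 975 | wl > 1646
  sd[edge] <- sd[edge] * spec$edge_noise_gain
  sd
}
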