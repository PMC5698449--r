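#' Labelled spectral dataset
#'
#' The tabular container for per-seed mean spectra: a tibble with one row
#' per seed, metadata columns `seed_id`, `variety` and `class` (1 = wild
#' type, 2 = mutant), and a matrix column `spectra` whose columns are the
#' spectral bands (column names carry the wavelengths in nm). Because the
#' spectra live in a single matrix column, the dataset pipes through
#' dplyr verbs without losing its band structure.
#'
#' @param spectra numeric matrix, seeds x bands.
#' @param class integer labels in `{1, 2}`, one per row.
#' @param wavelengths band wavelengths in nm, one per column of `spectra`.
#' @param variety character scalar or vector of variety labels.
#' @param seed_id optional integer ids (default `1:n`).
#' @return A tibble of subclass `spectral_dataset`.
#' @examples
#' ds <- spectral_dataset(matrix(runif(12), 4, 3), c(1, 1, 2, 2),
#'                        wavelengths = c(900, 1000, 1100))
#' spectral_matrix(ds)
#' @export
spectral_dataset <- function(spectra, class, wavelengths,
                             variety = "synthetic", seed_id = NULL) {
  spectra <- as.matrix(spectra)
  class <- as.integer(class)
  if (nrow(spectra) != length(class)) {
    abort("`spectra` and `class` disagree on the number of seeds.")
  }
  if (ncol(spectra) != length(wavelengths)) {
    abort("`spectra` and `wavelengths` disagree on the number of bands.")
  }
  if (length(class) && !all(class %in% c(1L, 2L))) {
    abort("`class` labels must be 1 (wild type) or 2 (mutant).")
  }
  if (is.null(seed_id)) seed_id <- seq_len(nrow(spectra))
  colnames(spectra) <- format_wl(wavelengths)
  rownames(spectra) <- NULL
  out <- tibble(
    seed_id = as.integer(seed_id),
    variety = variety,
    class = class,
    spectra = spectra
  )
  class(out) <- c("spectral_dataset", class(out))
  out
}

format_wl <- function(wl) sprintf("%.4f", wl)

#' @rdname spectral_dataset
#' @param ds a `spectral_dataset`.
#' @export
spectral_matrix <- function(ds) {
  m <- ds$spectra
  if (is.null(m)) abort("`ds` has no `spectra` matrix column.")
  as.matrix(m)
}

#' @export
wavelengths.spectral_dataset <- function(x) as.numeric(colnames(x$spectra))

#' @export
wavelengths.default <- function(x) {
  wl <- attr(x, "wavelengths")
  if (is.null(wl)) abort("object carries no wavelength grid.")
  wl
}

#' Long-format view of a spectral dataset
#'
#' @param x a [spectral_dataset()].
#' @param ... unused.
#' @return A tibble with columns `seed_id`, `variety`, `class`,
#'   `wavelength`, `reflectance` (one row per seed and band).
#' @export
tidy.spectral_dataset <- function(x, ...) {
  m <- spectral_matrix(x)
  wl <- wavelengths(x)
  tibble(
    seed_id = rep(x$seed_id, times = ncol(m)),
    variety = rep(x$variety, times = ncol(m)),
    class = rep(x$class, times = ncol(m)),
    wavelength = rep(wl, each = nrow(m)),
    reflectance = as.vector(m)
  )
}

#' Write / read a spectral dataset as CSV + JSON sidecar
#'
#' The CSV is wide (one row per seed, one column per band named by its
#' wavelength); labels and variety go to `<path>.json`.
#'
#' @param ds a [spectral_dataset()].
#' @param path CSV file path.
#' @return `write_spectral_dataset()` returns `path` invisibly;
#'   `read_spectral_dataset()` the reconstructed dataset.
#' @export
write_spectral_dataset <- function(ds, path) {
  m <- spectral_matrix(ds)
  df <- data.frame(seed_id = ds$seed_id, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    variety = ds$variety, class = ds$class, seed_id = ds$seed_id,
    wavelengths = wavelengths(ds)
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_spectral_dataset
#' @export
read_spectral_dataset <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  spectral_dataset(m, side$class, side$wavelengths,
                   variety = side$variety, seed_id = df$seed_id)
}

#' Plot the spectra of a dataset
#'
#' One reflectance curve per seed, coloured by class.
#'
#' @param object a [spectral_dataset()].
#' @param alpha line transparency.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_dataset <- function(object, alpha = 0.3, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength, y = .data$reflectance,
    group = .data$seed_id, colour = factor(.data$class)
  )) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::scale_colour_manual(
      values = c(`1` = "#6B8E23", `2` = "#E69F00"),
      labels = c(`1` = "wild type", `2` = "mutant"), name = "class"
    ) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance")
}
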