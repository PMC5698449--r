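#' Exploratory principal component analysis of mean spectra
#'
#' Column-mean-centred PCA (no variance scaling, the convention for
#' reflectance spectra) via singular value decomposition. Loadings are
#' sign-fixed so each component's largest-magnitude element is positive,
#' which makes loading-peak picking reproducible. Explained percentages
#' are `100 * lambda_i / sum(lambda)` over all available components.
#'
#' @param x a [spectral_dataset()] or numeric matrix (samples x bands).
#' @param k number of components to retain (default 3).
#' @return An object of class `spectral_pca`: `mean_spectrum`, `loadings`
#'   (bands x k, orthonormal), `scores` (n x k), `explained_pct` (first
#'   `k`), `explained_pct_all`, plus `wavelengths`/`class` when `x` is a
#'   dataset.
#' @export
fit_pca <- function(x, k = 3) {
  wl <- NULL
  y <- NULL
  if (inherits(x, "spectral_dataset") ||
      (is.data.frame(x) && "spectra" %in% names(x))) {
    wl <- wavelengths(x)
    y <- x$class
    X <- spectral_matrix(x)
  } else {
    X <- as.matrix(x)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) abort("PCA needs at least 2 samples.")
  if (k < 1L || k > min(n - 1L, p)) {
    abort(sprintf("`k` must lie in [1, %d].", min(n - 1L, p)))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  total_var <- sum(Xc^2)
  if (total_var < 1e-24) {
    abort("degenerate data: zero total variance, PCA undefined.")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  explained_all <- 100 * ev / sum(ev)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| loading element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      mean_spectrum = ctr,
      loadings = load,
      scores = scores,
      explained_pct = explained_all[seq_len(k)],
      explained_pct_all = explained_all,
      k = k,
      wavelengths = wl,
      class = y
    ),
    class = "spectral_pca"
  )
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat(sprintf(
    "<spectral_pca> %d components; explained: %s\n", x$k,
    paste(sprintf("%.2f%%", x$explained_pct), collapse = ", ")
  ))
  invisible(x)
}

#' @export
wavelengths.spectral_pca <- function(x) {
  if (is.null(x$wavelengths)) abort("model carries no wavelength grid.")
  x$wavelengths
}

#' Summed explained variance of leading components
#'
#' For a fitted [fit_pca()] model, or directly for a vector of explained
#' percentages (handy for bookkeeping of reported values: components
#' `c(93.95, 5.31, 0.38)` sum to `99.64`).
#'
#' @param x a `spectral_pca` or numeric vector of percentages.
#' @param first_k how many leading components to sum.
#' @return A single percentage.
#' @export
explained_sum <- function(x, first_k) UseMethod("explained_sum")

#' @export
explained_sum.spectral_pca <- function(x, first_k = x$k) {
  explained_sum(x$explained_pct_all, first_k)
}

#' @export
explained_sum.numeric <- function(x, first_k = length(x)) {
  if (first_k < 1L || first_k > length(x)) {
    abort("`first_k` exceeds the number of components.")
  }
  sum(x[seq_len(first_k)])
}

#' @rdname fit_pca
#' @param x a `spectral_pca`.
#' @param matrix `"loadings"` (band weights) or `"scores"` (sample
#'   projections).
#' @param ... unused.
#' @export
tidy.spectral_pca <- function(x, matrix = c("loadings", "scores"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "loadings") {
    tibble(
      component = rep(seq_len(x$k), each = nrow(x$loadings)),
      band = rep(seq_len(nrow(x$loadings)), times = x$k),
      wavelength = if (is.null(x$wavelengths)) NA_real_ else
        rep(x$wavelengths, times = x$k),
      loading = as.vector(x$loadings)
    )
  } else {
    tibble(
      sample = rep(seq_len(nrow(x$scores)), times = x$k),
      class = if (is.null(x$class)) NA_integer_ else
        rep(x$class, times = x$k),
      component = rep(seq_len(x$k), each = nrow(x$scores)),
      score = as.vector(x$scores)
    )
  }
}

#' @export
glance.spectral_pca <- function(x, ...) {
  tibble(
    k = x$k,
    explained_pct = explained_sum(x, x$k),
    n = nrow(x$scores),
    n_bands = nrow(x$loadings)
  )
}

#' @rdname fit_pca
#' @param object a `spectral_pca`.
#' @export
autoplot.spectral_pca <- function(object, ...) {
  long <- tidy(object, matrix = "loadings")
  xvar <- if (all(is.na(long$wavelength))) "band" else "wavelength"
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data[[xvar]], y = .data$loading,
    colour = factor(.data$component)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (xvar == "wavelength") "wavelength (nm)" else "band",
      colour = "PC"
    )
}

#' Score plot of the leading components
#'
#' @param model a [fit_pca()] result fitted on a labelled dataset.
#' @param components length-2 integer, which components to plot.
#' @return A ggplot object.
#' @export
plot_scores <- function(model, components = c(1, 2)) {
  s <- model$scores[, components, drop = FALSE]
  df <- tibble(
    x = s[, 1L], y = s[, 2L],
    class = if (is.null(model$class)) factor(1) else factor(model$class)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC%d (%.2f%%)", components[1L],
                  model$explained_pct[components[1L]]),
      y = sprintf("PC%d (%.2f%%)", components[2L],
                  model$explained_pct[components[2L]])
    )
}
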