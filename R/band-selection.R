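#' Band selection results
#'
#' A `band_selection` is a tibble (`method`, `rank`, `band_index`,
#' `wavelength_nm`) with the selecting criterion trace attached as
#' attribute `"criterion_trace"` (SPA only: best validation RMSE per
#' subset size).
#'
#' @param method `"SPA"` or `"PCA_loadings"`.
#' @param indices ordered band indices.
#' @param wavelengths_nm wavelengths matching `indices` (may be `NA`).
#' @param criterion_trace optional tibble `m`, `rmsev`.
#' @return A `band_selection` tibble.
#' @keywords internal
new_band_selection <- function(method, indices, wavelengths_nm = NULL,
                               criterion_trace = NULL) {
  if (anyDuplicated(indices)) abort("selected band indices must be unique.")
  if (is.null(wavelengths_nm)) wavelengths_nm <- rep(NA_real_, length(indices))
  out <- tibble(
    method = method,
    rank = seq_along(indices),
    band_index = as.integer(indices),
    wavelength_nm = as.numeric(wavelengths_nm)
  )
  class(out) <- c("band_selection", class(out))
  attr(out, "criterion_trace") <- criterion_trace
  out
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> %s: %d bands\n", x$method[1L], nrow(x)))
  NextMethod()
}

band_indices <- function(bands, p = NULL) {
  idx <- if (inherits(bands, "band_selection")) bands$band_index
         else as.integer(bands)
  if (!is.null(p) && any(idx < 1L | idx > p)) {
    abort("band indices out of range for this dataset.")
  }
  idx
}

#' Successive projections chain
#'
#' The core SPA recursion: starting from one column of `X`, repeatedly
#' append the column whose projection onto the orthogonal complement of
#' the span of the already-chosen columns has the largest norm. This
#' yields a minimally collinear candidate chain; subset size and start are
#' chosen elsewhere ([spa_select()]) by validation error. Ties resolve to
#' the lowest column index; if the residual space degenerates before
#' `chain_length` columns are found, the chain is truncated with a
#' warning.
#'
#' @param X numeric matrix (samples x bands), typically mean-centred
#'   calibration spectra.
#' @param start_index first column of the chain.
#' @param chain_length requested chain length
#'   (`<= min(nrow(X) - 1, ncol(X))`).
#' @return Integer vector of column indices in selection order.
#' @export
spa_chain <- function(X, start_index, chain_length) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (start_index < 1L || start_index > p) abort("`start_index` out of range.")
  if (chain_length < 1L || chain_length > min(nrow(X) - 1L, p)) {
    abort(sprintf("`chain_length` must lie in [1, %d].",
                  min(nrow(X) - 1L, p)))
  }
  R <- X
  tol <- max(colSums(X^2)) * 1e-12
  chain <- integer(0L)
  active <- rep(TRUE, p)
  j <- as.integer(start_index)
  for (step in seq_len(chain_length)) {
    chain <- c(chain, j)
    active[j] <- FALSE
    u <- R[, j]
    nrm2 <- sum(u^2)
    if (nrm2 > 0) {
      u <- u / sqrt(nrm2)
      R <- R - u %*% crossprod(u, R)
    }
    if (step == chain_length) break
    norms <- colSums(R^2)
    norms[!active] <- -Inf
    if (max(norms) <= tol) {
      warn(sprintf(
        "SPA residual space exhausted after %d of %d bands; chain truncated.",
        step, chain_length
      ))
      break
    }
    j <- which.max(norms)
  }
  chain
}

#' SPA wavelength selection with an MLR validation-RMSE criterion
#'
#' Full successive-projections selection: for every possible starting band
#' and every subset size `m <= max_vars`, the first `m` bands of the SPA
#' chain are used as regressors in an ordinary least squares fit of the
#' numeric class labels (1/2) on the calibration set; the subset
#' minimising the root-mean-square error on the validation set (RMSEV) is
#' returned. Ties prefer fewer bands, then the lower starting index.
#' Chains are computed on mean-centred calibration spectra.
#'
#' @param Xcal,ycal calibration spectra and numeric labels.
#' @param Xval,yval validation spectra and labels (never the final
#'   prediction set: use an inner split of the calibration data).
#' @param max_vars largest subset size considered (default 15).
#' @param wavelengths_nm optional wavelengths for reporting.
#' @return A `band_selection` with the winning chain prefix (in selection
#'   order) and the per-size best-RMSEV trace.
#' @export
spa_select <- function(Xcal, ycal, Xval, yval, max_vars = 15,
                       wavelengths_nm = NULL) {
  Xcal <- as.matrix(Xcal)
  Xval <- as.matrix(Xval)
  if (nrow(Xval) == 0L) abort("validation set is empty.")
  if (max_vars < 1L) abort("`max_vars` must be >= 1.")
  p <- ncol(Xcal)
  max_vars <- min(max_vars, nrow(Xcal) - 1L, p)
  Xc <- sweep(Xcal, 2L, colMeans(Xcal))

  best <- list(rmsev = Inf, m = NA_integer_, start = NA_integer_,
               chain = integer(0L))
  trace <- rep(Inf, max_vars)
  for (start in seq_len(p)) {
    chain <- suppressWarnings(spa_chain(Xc, start, max_vars))
    for (m in seq_along(chain)) {
      idx <- chain[seq_len(m)]
      rmsev <- mlr_rmsev(Xcal[, idx, drop = FALSE], ycal,
                         Xval[, idx, drop = FALSE], yval)
      if (rmsev < trace[m]) trace[m] <- rmsev
      better <- rmsev < best$rmsev - 1e-12 ||
        (abs(rmsev - best$rmsev) <= 1e-12 &&
           (m < best$m || (m == best$m && start < best$start)))
      if (better) {
        best <- list(rmsev = rmsev, m = m, start = start,
                     chain = idx)
      }
    }
  }
  wl <- if (is.null(wavelengths_nm)) NULL else wavelengths_nm[best$chain]
  new_band_selection(
    "SPA", best$chain, wl,
    criterion_trace = tibble(m = seq_len(max_vars), rmsev = trace)
  )
}

# OLS of y on X (+ intercept) fitted on cal, RMSE on val. Rank-deficient
# designs fall back to a small fixed ridge.
mlr_rmsev <- function(Xcal, ycal, Xval, yval) {
  A <- cbind(1, Xcal)
  fit <- stats::lm.fit(A, ycal)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    lambda <- 1e-8
    G <- crossprod(A) + diag(lambda, ncol(A))
    coefs <- solve(G, crossprod(A, ycal))
  }
  pred <- cbind(1, Xval) %*% coefs
  sqrt(mean((yval - pred)^2))
}

#' Peak/valley picking on PCA loading curves
#'
#' Treats each of the first `n_components` loading curves as a spectrum
#' and selects all strict local maxima and minima whose topographic
#' prominence reaches `prominence` (by default 5% of that curve's range).
#' Selections from all components are pooled, de-duplicated (extrema
#' within one band of each other merge, keeping the more prominent) and
#' sorted by wavelength.
#'
#' @param model a [fit_pca()] result.
#' @param n_components how many leading components to scan.
#' @param prominence absolute prominence threshold, or `NULL` for 5% of
#'   each curve's range.
#' @return A `band_selection` (method `"PCA_loadings"`).
#' @export
loading_peaks <- function(model, n_components = 3, prominence = NULL) {
  if (!inherits(model, "spectral_pca")) abort("`model` must be a spectral_pca.")
  if (n_components > model$k) {
    abort("`n_components` exceeds the fitted components.")
  }
  hits <- list()
  for (j in seq_len(n_components)) {
    v <- model$loadings[, j]
    thr <- if (is.null(prominence)) 0.05 * diff(range(v)) else prominence
    ex <- local_extrema(v)
    if (nrow(ex) == 0L) next
    ex$prom <- vapply(seq_len(nrow(ex)), function(i) {
      extremum_prominence(v, ex$index[i], ex$type[i])
    }, numeric(1))
    ex <- ex[ex$prom >= thr, , drop = FALSE]
    hits[[j]] <- ex
  }
  hits <- dplyr::bind_rows(hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(new_band_selection("PCA_loadings", integer(0L),
                              wavelengths_nm = numeric(0L)))
  }
  hits <- hits[order(hits$index, -hits$prom), , drop = FALSE]
  # merge near-duplicates within one band, keeping the more prominent
  keep <- integer(0L)
  for (i in order(-hits$prom)) {
    if (all(abs(hits$index[i] - hits$index[keep]) > 1L) || !length(keep)) {
      keep <- c(keep, i)
    }
  }
  idx <- sort(unique(hits$index[keep]))
  wl <- if (is.null(model$wavelengths)) NULL else model$wavelengths[idx]
  new_band_selection("PCA_loadings", idx, wl)
}

# strict one-neighbour extrema (interior points only)
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) {
    return(tibble(index = integer(), type = character()))
  }
  i <- 2L:(n - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  tibble(
    index = c(i[is_max], i[is_min]),
    type = rep(c("max", "min"), c(sum(is_max), sum(is_min)))
  )
}

# topographic prominence: height above the higher of the two key saddles
# (for minima: computed on the negated curve)
extremum_prominence <- function(v, i, type) {
  if (type == "min") v <- -v
  n <- length(v)
  left_min <- Inf
  j <- i - 1L
  while (j >= 1L && v[j] <= v[i]) {
    left_min <- min(left_min, v[j])
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(left_min, v[i])  # ran to the boundary
  right_min <- Inf
  j <- i + 1L
  while (j <= n && v[j] <= v[i]) {
    right_min <- min(right_min, v[j])
    j <- j + 1L
  }
  if (j > n) right_min <- min(right_min, v[i])
  base <- max(left_min, right_min)
  if (!is.finite(base)) base <- v[i]
  v[i] - base
}

#' Select informative wavelengths from a calibration dataset
#'
#' Tidy front-end over [spa_select()] and [loading_peaks()]. For SPA the
#' calibration data are sub-split 2:1 by [kennard_stone()] into an inner
#' calibration/validation pair, so the final prediction set never
#' influences selection. For `"loadings"` a PCA is fitted on the
#' calibration spectra and its loading extrema picked.
#'
#' @param ds_cal calibration [spectral_dataset()] (e.g.
#'   [calibration_set()] of a [ks_split()]).
#' @param method `"spa"` or `"loadings"`.
#' @param max_vars largest SPA subset size.
#' @param n_components,prominence see [loading_peaks()].
#' @return A `band_selection`.
#' @export
select_bands <- function(ds_cal, method = c("spa", "loadings"),
                         max_vars = 15, n_components = 3,
                         prominence = NULL) {
  method <- match.arg(method)
  X <- spectral_matrix(ds_cal)
  wl <- wavelengths(ds_cal)
  if (method == "spa") {
    n <- nrow(X)
    n_inner <- as.integer(round_half_up(n * 2 / 3))
    inner <- kennard_stone(X, n_inner)
    val <- setdiff(seq_len(n), inner)
    spa_select(X[inner, , drop = FALSE], as.numeric(ds_cal$class[inner]),
               X[val, , drop = FALSE], as.numeric(ds_cal$class[val]),
               max_vars = max_vars, wavelengths_nm = wl)
  } else {
    loading_peaks(fit_pca(ds_cal, k = n_components),
                  n_components = n_components, prominence = prominence)
  }
}

#' Write a band selection as CSV (and JSON sidecar)
#'
#' @param bands a `band_selection`.
#' @param path CSV path; a `.json` twin is written alongside.
#' @return `path`, invisibly.
#' @export
write_band_selection <- function(bands, path) {
  utils::write.csv(as.data.frame(bands), path, row.names = FALSE)
  jsonlite::write_json(
    list(method = bands$method[1L], band_index = bands$band_index,
         wavelength_nm = bands$wavelength_nm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
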