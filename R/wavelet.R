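# Daubechies-8 discrete wavelet transform (16-tap orthogonal filters) with
# symmetric (edge-repeating) boundary extension, plus soft-threshold
# denoising. Standard filter-bank constants.

DB8_DEC_LO <- c(
  -0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705,
  -0.004870352993451574, 0.008746094047405777, 0.013981027917398282,
  -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
  0.0004724845739132828, -0.2840155429615469, -0.015829105256349306,
  0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
  0.05441584224310401
)
DB8_DEC_HI <- rev(DB8_DEC_LO) * rep_len(c(-1, 1), 16L)
DB8_LEN <- 16L

conv_full <- function(x, f) {
  n <- length(x)
  out <- numeric(n + length(f) - 1L)
  for (j in seq_along(f)) {
    idx <- j:(j + n - 1L)
    out[idx] <- out[idx] + f[j] * x
  }
  out
}

dwt_step <- function(x) {
  n <- length(x)
  L <- DB8_LEN
  ext <- c(x[(L - 1L):1L], x, x[n:(n - L + 2L)])
  nc <- (n + L - 1L) %/% 2L
  idx <- seq(L + 1L, by = 2L, length.out = nc)
  list(ca = conv_full(ext, DB8_DEC_LO)[idx],
       cd = conv_full(ext, DB8_DEC_HI)[idx])
}

idwt_step <- function(ca, cd, n_out) {
  L <- DB8_LEN
  nc <- length(ca)
  up_a <- numeric(2L * nc)
  up_a[seq(1L, 2L * nc, 2L)] <- ca
  up_d <- numeric(2L * nc)
  up_d[seq(1L, 2L * nc, 2L)] <- cd
  y <- conv_full(up_a, rev(DB8_DEC_LO)) + conv_full(up_d, rev(DB8_DEC_HI))
  y[(L - 1L):(L - 2L + n_out)]
}

# Multilevel decomposition; keeps per-level lengths for exact reconstruction.
db8_wavedec <- function(x, level) {
  details <- vector("list", level)
  lens <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    if (length(a) < DB8_LEN - 1L) {
      abort(sprintf(
        "spectrum too short for level-%d db8 decomposition: length %d at level %d, need >= %d.",
        level, length(a), l, DB8_LEN - 1L
      ))
    }
    lens[l] <- length(a)
    s <- dwt_step(a)
    a <- s$ca
    details[[l]] <- s$cd
  }
  list(ca = a, cd = details, lens = lens)
}

db8_waverec <- function(dec) {
  a <- dec$ca
  for (l in rev(seq_along(dec$cd))) {
    a <- idwt_step(a, dec$cd[[l]], dec$lens[l])
  }
  a
}

#' Wavelet denoising of reflectance spectra
#'
#' Suppresses measurement noise by a level-`level` Daubechies-8 wavelet
#' decomposition, soft thresholding of all detail coefficients, and
#' reconstruction. The threshold is the universal threshold
#' `sigma * sqrt(2 * log(n))` with `sigma` estimated from the finest-level
#' detail coefficients via `MAD / 0.6745`. Boundaries use symmetric
#' (edge-repeating) extension. A constant spectrum passes through
#' unchanged; smooth spectra are perturbed only marginally.
#'
#' @param x numeric vector (one spectrum), matrix (spectra in rows) or
#'   [spectral_dataset()].
#' @param level decomposition depth (default 3).
#' @param threshold `"universal_soft"` (default) or `"none"` (pure
#'   decompose/reconstruct round trip).
#' @param ... passed between methods.
#' @return Same shape/class as `x`, denoised.
#' @export
wavelet_denoise <- function(x, ...) UseMethod("wavelet_denoise")

#' @rdname wavelet_denoise
#' @export
wavelet_denoise.numeric <- function(x, level = 3,
                                    threshold = c("universal_soft", "none"),
                                    ...) {
  threshold <- match.arg(threshold)
  n <- length(x)
  dec <- db8_wavedec(x, level)
  if (threshold == "universal_soft") {
    sigma <- stats::mad(dec$cd[[1L]], center = 0, constant = 1) / 0.6745
    thr <- sigma * sqrt(2 * log(n))
    if (thr > 0) {
      dec$cd <- lapply(dec$cd, soft_threshold, thr = thr)
    }
  }
  db8_waverec(dec)
}

#' @rdname wavelet_denoise
#' @export
wavelet_denoise.matrix <- function(x, level = 3,
                                   threshold = c("universal_soft", "none"),
                                   ...) {
  threshold <- match.arg(threshold)
  out <- t(apply(x, 1L, wavelet_denoise.numeric,
                 level = level, threshold = threshold))
  dimnames(out) <- dimnames(x)
  out
}

#' @rdname wavelet_denoise
#' @export
wavelet_denoise.spectral_dataset <- function(x, level = 3,
                                             threshold = c("universal_soft",
                                                           "none"), ...) {
  threshold <- match.arg(threshold)
  x$spectra <- wavelet_denoise.matrix(spectral_matrix(x), level = level,
                                      threshold = threshold)
  x
}

soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)
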