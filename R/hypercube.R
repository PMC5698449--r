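#' Hyperspectral cube
#'
#' A hypercube is a three-dimensional raster of intensities (`kind = "raw"`)
#' or relative reflectances (`kind = "reflectance"`): two spatial axes
#' (rows, columns) and one spectral axis with a strictly increasing
#' wavelength vector in nanometres. Dark/white reference recordings from a
#' push-broom line scanner are represented as single-row cubes and are
#' broadcast across rows wherever a full cube is expected.
#'
#' @param data numeric array `rows x cols x bands`.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per band.
#' @param kind `"raw"` for sensor counts, `"reflectance"` for calibrated data.
#' @return An object of class `hypercube`.
#' @examples
#' cube <- hypercube(array(0.5, c(4, 4, 3)), c(900, 1000, 1100), "reflectance")
#' n_bands(cube)
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array (rows x cols x bands).")
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L) {
    abort("a hypercube needs at least 2 spectral bands.")
  }
  if (dim(data)[3L] != length(wavelengths)) {
    abort(sprintf(
      "band dimension (%d) does not match wavelength vector length (%d).",
      dim(data)[3L], length(wavelengths)
    ))
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing.")
  }
  if (kind == "reflectance" && any(is.nan(data) | is.infinite(data))) {
    abort("reflectance cubes must not contain NaN or infinite values.")
  }
  structure(
    list(data = data, wavelengths = wavelengths, kind = kind),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d px, %d bands (%.2f-%.2f nm), kind: %s\n",
    d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths), x$kind
  ))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Number of spectral bands
#' @param cube a [hypercube()].
#' @return integer count of bands.
#' @export
n_bands <- function(cube) length(cube$wavelengths)

#' Wavelength vector of an object
#'
#' @param x a [hypercube()], [spectral_dataset()] or fitted model carrying a
#'   wavelength grid.
#' @return numeric vector of wavelengths in nm.
#' @export
wavelengths <- function(x) UseMethod("wavelengths")

#' @export
wavelengths.hypercube <- function(x) x$wavelengths

#' Dark/white reflectance calibration
#'
#' Converts raw intensity counts to relative reflectance with the two-point
#' reference correction `rho = (raw - dark) / (white - dark)`, applied
#' elementwise. The dark reference is recorded with the light path blocked
#' (dark current), the white reference against a near-100% reflectance
#' standard. References may be full cubes or single-row scanline frames
#' (broadcast across image rows).
#'
#' Pixels/bands whose white-minus-dark difference is smaller in magnitude
#' than `epsilon` carry no usable dynamic range. By default they are set to
#' `NA` (sentinel) with a warning; with `on_bad_pixel = "error"` they abort.
#'
#' @param raw raw-intensity [hypercube()].
#' @param dark,white reference cubes sharing `raw`'s wavelength grid; either
#'   full-size or single-row.
#' @param epsilon denominator guard; defaults to `1e-6` of the median white
#'   level.
#' @param on_bad_pixel `"sentinel"` (default) or `"error"`.
#' @return A reflectance [hypercube()]; the number of flagged pixels is
#'   attached as attribute `"n_flagged"`.
#' @examples
#' wl <- c(900, 1000)
#' raw <- hypercube(array(60, c(2, 2, 2)), wl)
#' dark <- hypercube(array(20, c(2, 2, 2)), wl)
#' white <- hypercube(array(100, c(2, 2, 2)), wl)
#' calibrate(raw, dark, white)$data[1, 1, ]  # 0.5 0.5
#' @export
calibrate <- function(raw, dark, white, epsilon = NULL,
                      on_bad_pixel = c("sentinel", "error")) {
  on_bad_pixel <- match.arg(on_bad_pixel)
  for (nm in c("raw", "dark", "white")) {
    if (!inherits(get(nm), "hypercube")) {
      abort(sprintf("`%s` must be a hypercube.", nm))
    }
  }
  wl <- raw$wavelengths
  if (!isTRUE(all.equal(wl, dark$wavelengths, tolerance = 1e-8)) ||
      !isTRUE(all.equal(wl, white$wavelengths, tolerance = 1e-8))) {
    abort("raw, dark and white cubes must share one wavelength grid.")
  }
  d <- dim(raw$data)
  if (is.null(epsilon)) epsilon <- 1e-6 * stats::median(white$data)

  single_row <- function(ref) {
    rd <- dim(ref$data)
    ok <- rd[1L] == 1L && rd[2L] == d[2L] && rd[3L] == d[3L]
    if (!ok && !identical(rd, d)) {
      abort(sprintf(
        "reference dimensions (%s) are incompatible with raw dimensions (%s).",
        paste(rd, collapse = "x"), paste(d, collapse = "x")
      ))
    }
    ok
  }

  if (single_row(dark) && single_row(white)) {
    # scanline references: work band by band against cols x bands frames
    dk_f <- matrix(dark$data, d[2L], d[3L])
    wh_f <- matrix(white$data, d[2L], d[3L])
    denom_f <- wh_f - dk_f
    n_bad <- sum(abs(denom_f) <= epsilon) * d[1L]
    check_bad(n_bad, epsilon, on_bad_pixel)
    rho <- array(0, d)
    for (b in seq_len(d[3L])) {
      dkb <- matrix(dk_f[, b], d[1L], d[2L], byrow = TRUE)
      dnb <- matrix(denom_f[, b], d[1L], d[2L], byrow = TRUE)
      plane <- (raw$data[, , b] - dkb) / dnb
      if (n_bad > 0L) plane[matrix(abs(denom_f[, b]) <= epsilon,
                                   d[1L], d[2L], byrow = TRUE)] <- NA_real_
      rho[, , b] <- plane
    }
  } else {
    dk <- broadcast_reference(dark, d)
    wh <- broadcast_reference(white, d)
    denom <- wh - dk
    bad <- abs(denom) <= epsilon
    n_bad <- sum(bad)
    check_bad(n_bad, epsilon, on_bad_pixel)
    rho <- (raw$data - dk) / denom
    if (n_bad > 0L) rho[bad] <- NA_real_
  }
  out <- hypercube(rho, wl, kind = "reflectance")
  attr(out, "n_flagged") <- n_bad
  out
}

check_bad <- function(n_bad, epsilon, on_bad_pixel) {
  if (n_bad == 0L) return(invisible())
  msg <- sprintf(
    "%d pixel/band entries have |white - dark| <= epsilon (%.3g).",
    n_bad, epsilon
  )
  if (on_bad_pixel == "error") abort(msg) else warn(paste(msg, "Set to NA."))
  invisible()
}

# Expand a (possibly single-row) reference cube to the target dimensions.
broadcast_reference <- function(ref, target_dim) {
  rd <- dim(ref$data)
  if (identical(rd, target_dim)) {
    return(ref$data)
  }
  if (rd[1L] == 1L && rd[2L] == target_dim[2L] && rd[3L] == target_dim[3L]) {
    return(ref$data[rep(1L, target_dim[1L]), , , drop = FALSE])
  }
  abort(sprintf(
    "reference dimensions (%s) are incompatible with raw dimensions (%s).",
    paste(rd, collapse = "x"), paste(target_dim, collapse = "x")
  ))
}

#' Restrict a cube to a spectral range
#'
#' Keeps exactly the bands whose wavelength lies in the closed interval
#' `[lo_nm, hi_nm]`. Useful to discard noisy sensor back-end channels (the
#' analyses here use 975-1646 nm by default).
#'
#' @param cube a [hypercube()] or [spectral_dataset()].
#' @param lo_nm,hi_nm interval endpoints in nm, `lo_nm < hi_nm`.
#' @return The input with the cropped band set.
#' @export
crop_spectral_range <- function(cube, lo_nm, hi_nm) {
  stopifnot_scalar_number(lo_nm, "lo_nm")
  stopifnot_scalar_number(hi_nm, "hi_nm")
  if (lo_nm >= hi_nm) abort("`lo_nm` must be smaller than `hi_nm`.")
  UseMethod("crop_spectral_range")
}

#' @export
crop_spectral_range.hypercube <- function(cube, lo_nm, hi_nm) {
  keep <- cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm
  if (!any(keep)) {
    abort(sprintf("no bands fall inside [%.2f, %.2f] nm.", lo_nm, hi_nm))
  }
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            kind = cube$kind)
}

#' @export
crop_spectral_range.spectral_dataset <- function(cube, lo_nm, hi_nm) {
  wl <- wavelengths(cube)
  keep <- wl >= lo_nm & wl <= hi_nm
  if (!any(keep)) {
    abort(sprintf("no bands fall inside [%.2f, %.2f] nm.", lo_nm, hi_nm))
  }
  cube$spectra <- cube$spectra[, keep, drop = FALSE]
  cube
}

#' Extract the band nearest a target wavelength
#'
#' Returns the single-band greyscale image whose wavelength is closest to
#' `target_nm` (the default, 1139.26 nm, gives good seed/background contrast
#' on rice). A target exactly midway between two bands resolves to the lower
#' wavelength.
#'
#' @param cube a calibrated [hypercube()].
#' @param target_nm target wavelength in nm.
#' @return A numeric matrix with attributes `wavelength` and `band_index`.
#' @export
select_segmentation_band <- function(cube, target_nm = 1139.26) {
  stopifnot_scalar_number(target_nm, "target_nm")
  idx <- which.min(abs(cube$wavelengths - target_nm))  # first = lower on ties
  out <- cube$data[, , idx]
  attr(out, "wavelength") <- cube$wavelengths[idx]
  attr(out, "band_index") <- idx
  out
}
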