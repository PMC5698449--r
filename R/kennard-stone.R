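#' Kennard-Stone sample selection
#'
#' Deterministic max-min-distance selection of a calibration subset: the
#' first two samples are the pair at maximum Euclidean distance; every
#' further sample maximises its minimum distance to the already-selected
#' set. Ties resolve to the lowest row index, so the selection depends
#' only on the data. The selection is nested: the first `k` entries of the
#' returned order are the `n_cal = k` calibration set.
#'
#' @param X numeric matrix, samples in rows.
#' @param n_cal number of calibration samples, between 2 and `nrow(X) - 1`.
#' @return Integer vector of length `n_cal`: selected row indices in
#'   selection order.
#' @examples
#' kennard_stone(cbind(0:3), 2)  # the farthest pair: rows 1 and 4
#' @export
kennard_stone <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_cal < 2L || n_cal > n - 1L) {
    abort(sprintf("`n_cal` must lie in [2, %d]; got %s.", n - 1L, n_cal))
  }
  D <- unname(as.matrix(dist(X)))
  # farthest pair, lexicographically smallest on ties
  mx <- max(D)
  hits <- which(D >= mx - 0, arr.ind = TRUE)
  hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  sel <- as.integer(hits[1L, ])
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  in_sel <- logical(n)
  in_sel[sel] <- TRUE
  while (length(sel) < n_cal) {
    cand <- mind
    cand[in_sel] <- -Inf
    nxt <- which.max(cand)  # first index on ties
    sel <- c(sel, nxt)
    in_sel[nxt] <- TRUE
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

#' Split a spectral dataset into calibration and prediction sets
#'
#' Applies [kennard_stone()] at a `cal:pred` ratio (default 2:1, the
#' convention for these seed studies: 660 seeds split into 440 + 220).
#' The calibration size is `round(n * r / (r + 1))` with half-up rounding.
#'
#' @param ds a [spectral_dataset()] (or any tibble with a `spectra` matrix
#'   column).
#' @param ratio length-2 numeric `c(cal, pred)` proportions.
#' @return `ds` with a new factor column `set`
#'   (`"calibration"`/`"prediction"`); the selection order is attached as
#'   attribute `"ks_order"`.
#' @export
ks_split <- function(ds, ratio = c(2, 1)) {
  if (length(ratio) != 2L || any(ratio <= 0)) {
    abort("`ratio` must be two positive numbers, e.g. c(2, 1).")
  }
  n <- nrow(ds)
  n_cal <- as.integer(round_half_up(n * ratio[1L] / sum(ratio)))
  order_sel <- kennard_stone(spectral_matrix(ds), n_cal)
  set <- rep("prediction", n)
  set[order_sel] <- "calibration"
  ds$set <- factor(set, levels = c("calibration", "prediction"))
  attr(ds, "ks_order") <- order_sel
  ds
}

#' @rdname ks_split
#' @export
calibration_set <- function(ds) ds[ds$set == "calibration", , drop = FALSE]

#' @rdname ks_split
#' @export
prediction_set <- function(ds) ds[ds$set == "prediction", , drop = FALSE]
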