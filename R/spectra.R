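#' Mean spectrum of a seed's region of interest
#'
#' Averages the calibrated reflectance over all pixels of one seed mask:
#' the per-seed sample spectrum used everywhere downstream.
#'
#' @param cube a calibrated [hypercube()].
#' @param mask full-size logical mask of the seed (e.g. [seed_mask()]).
#' @return Numeric vector, one mean reflectance per band.
#' @export
mean_spectrum <- function(cube, mask) {
  if (!inherits(cube, "hypercube")) abort("`cube` must be a hypercube.")
  d <- dim(cube$data)
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2])) {
    abort("`mask` must be a logical matrix matching the cube's spatial size.")
  }
  px <- which(mask != 0)
  if (length(px) == 0L) abort("`mask` is empty.")
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])
  colMeans(m[px, , drop = FALSE])
}

# Mean spectra of all segmented objects at once (rows = objects, in
# object_id order). Used by build_dataset() and predict_map().
object_mean_spectra <- function(cube, seg) {
  d <- dim(cube$data)
  lab <- seg$labels
  if (!identical(dim(lab), d[1:2])) {
    abort("segmentation raster does not match the cube's spatial size.")
  }
  ids <- seg$objects$object_id
  if (length(ids) == 0L) {
    return(matrix(numeric(), 0L, d[3L]))
  }
  px <- which(lab > 0L)
  groups <- lab[px]
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])
  sums <- rowsum(m[px, , drop = FALSE], group = groups, reorder = TRUE)
  counts <- as.vector(table(factor(groups, levels = sort(unique(groups)))))
  out <- sums / counts
  out[match(ids, sort(unique(groups))), , drop = FALSE]
}

#' Assemble the labelled spectral matrix from a segmented cube
#'
#' Runs the spectral-extraction stage of the pipeline: per-seed ROI mean
#' spectra (object-wise averaging), optional restriction to the clean
#' spectral range, and optional wavelet denoising, assembled into a
#' [spectral_dataset()] in `object_id` order.
#'
#' @param cube a calibrated [hypercube()].
#' @param seg a [segment_seeds()] result.
#' @param labels integer class labels (1 = wild type, 2 = mutant), one per
#'   segmented object, in `object_id` order.
#' @param variety variety tag stored in the dataset.
#' @param crop_range length-2 nm interval to keep (default `c(975, 1646)`),
#'   or `NULL` to keep all bands.
#' @param denoise apply [wavelet_denoise()] to each row?
#' @return A [spectral_dataset()] with one row per segmented seed.
#' @export
build_dataset <- function(cube, seg, labels, variety = "unknown",
                          crop_range = c(975, 1646), denoise = TRUE) {
  if (!inherits(seg, "seed_segmentation")) {
    abort("`seg` must be a seed_segmentation.")
  }
  n_obj <- nrow(seg$objects)
  if (length(labels) != n_obj) {
    abort(sprintf("%d labels supplied for %d segmented objects.",
                  length(labels), n_obj))
  }
  if (!is.null(crop_range)) {
    cube <- crop_spectral_range(cube, crop_range[1L], crop_range[2L])
  }
  X <- object_mean_spectra(cube, seg)
  if (denoise && n_obj > 0L) {
    X <- wavelet_denoise(X)
  }
  spectral_dataset(X, labels, cube$wavelengths, variety = variety,
                   seed_id = seg$objects$object_id)
}

#' Match segmented objects to planted seeds
#'
#' For synthetic scenes: assigns each segmented object the planted seed id
#' owning the majority of its pixels, giving access to ground-truth
#' classes for segmented objects.
#'
#' @param seg a [segment_seeds()] result.
#' @param truth_labels the scene's planted label raster
#'   (`scene$labels`).
#' @return A tibble `object_id`, `seed_id` (NA when an object overlaps no
#'   planted seed).
#' @export
match_truth <- function(seg, truth_labels) {
  if (!identical(dim(seg$labels), dim(truth_labels))) {
    abort("segmentation and truth rasters differ in size.")
  }
  purrr::map_dfr(seg$objects$object_id, function(id) {
    planted <- truth_labels[seg$labels == id]
    planted <- planted[planted > 0L]
    tibble(
      object_id = id,
      seed_id = if (length(planted)) {
        as.integer(names(which.max(table(planted))))
      } else {
        NA_integer_
      }
    )
  })
}
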