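#' Object-wise classification map
#'
#' Applies a trained classifier to every segmented seed of a calibrated
#' cube: the seed's mean spectrum is extracted with exactly the
#' preprocessing used for training (spectral crop, wavelet denoising, band
#' restriction), predicted once, and the predicted class painted over all
#' of the seed's pixels. Background pixels stay 0.
#'
#' @param cube a calibrated [hypercube()].
#' @param seg a [segment_seeds()] result on the same scene.
#' @param model a fitted `seed_classifier`.
#' @param colour_table named character vector mapping class labels to
#'   colours; must cover every predicted class. Defaults echo the olive
#'   (wild type) / orange (mutant) convention of seed prediction maps.
#' @param crop_range,denoise preprocessing applied before prediction; must
#'   match the training pipeline (defaults match [build_dataset()]).
#' @return A `prediction_map`: `label_raster` (0 = background),
#'   `per_seed` tibble (`object_id`, `pred_class`), `colour_table`.
#' @export
predict_map <- function(cube, seg, model,
                        colour_table = c(`1` = "#6B8E23", `2` = "#FFA500"),
                        crop_range = c(975, 1646), denoise = TRUE) {
  if (!inherits(seg, "seed_segmentation")) {
    abort("`seg` must be a seed_segmentation.")
  }
  n_obj <- nrow(seg$objects)
  if (n_obj == 0L) {
    warn("no segmented seeds: the map is all background.")
    return(new_prediction_map(seg$labels * 0L, tibble(
      object_id = integer(), pred_class = integer()
    ), colour_table))
  }
  if (!is.null(crop_range)) {
    cube <- crop_spectral_range(cube, crop_range[1L], crop_range[2L])
  }
  X <- object_mean_spectra(cube, seg)
  if (denoise) X <- wavelet_denoise(X)
  pred <- predict(model, X)
  missing_cols <- setdiff(as.character(unique(pred)), names(colour_table))
  if (length(missing_cols)) {
    abort(sprintf("colour_table lacks entries for predicted class(es): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  raster <- seg$labels
  lut <- integer(max(seg$objects$object_id))
  lut[seg$objects$object_id] <- pred
  raster[raster > 0L] <- lut[raster[raster > 0L]]
  new_prediction_map(
    raster,
    tibble(object_id = seg$objects$object_id, pred_class = as.integer(pred)),
    colour_table
  )
}

new_prediction_map <- function(label_raster, per_seed, colour_table) {
  structure(
    list(label_raster = label_raster, per_seed = per_seed,
         colour_table = colour_table),
    class = "prediction_map"
  )
}

#' @export
print.prediction_map <- function(x, ...) {
  counts <- table(x$per_seed$pred_class)
  cat(sprintf("<prediction_map> %d seeds (%s)\n", nrow(x$per_seed),
              paste(sprintf("class %s: %d", names(counts), counts),
                    collapse = ", ")))
  invisible(x)
}

#' Per-class accuracy of a prediction map
#'
#' @param map a [predict_map()] result.
#' @param truth tibble with columns `object_id` and `class` (true labels);
#'   must cover every mapped object.
#' @return A tibble per true class: `class`, `n`, `n_correct`,
#'   `accuracy` (percent).
#' @export
map_accuracy <- function(map, truth) {
  if (!all(c("object_id", "class") %in% names(truth))) {
    abort("`truth` needs columns `object_id` and `class`.")
  }
  unknown <- setdiff(map$per_seed$object_id, truth$object_id)
  if (length(unknown)) {
    abort(sprintf("truth table lacks object id(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  joined <- dplyr::inner_join(map$per_seed, truth[, c("object_id", "class")],
                              by = "object_id")
  joined |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(.data$pred_class == .data$class),
      accuracy = 100 * .data$n_correct / .data$n
    ) |>
    dplyr::ungroup()
}

#' Render a prediction map to RGB
#'
#' @param map a [predict_map()] result.
#' @param background colour of non-seed pixels.
#' @return rows x cols x 3 numeric array in \[0, 1\].
#' @export
render_map <- function(map, background = "#000000") {
  classes <- sort(unique(map$label_raster[map$label_raster > 0L]))
  pal <- grDevices::col2rgb(c(background, map$colour_table)) / 255
  colnames(pal) <- c("0", names(map$colour_table))
  d <- dim(map$label_raster)
  key <- as.character(map$label_raster)
  out <- array(0, c(d[1L], d[2L], 3L))
  for (ch in 1:3) {
    out[, , ch] <- matrix(pal[ch, key], d[1L], d[2L])
  }
  out
}

#' @rdname render_map
#' @param path PNG path.
#' @export
write_map_png <- function(map, path) {
  png::writePNG(render_map(map), path)
  invisible(path)
}

#' @rdname render_map
#' @export
write_label_raster <- function(map, path) {
  # 16-bit greyscale PNG of the class labels
  png::writePNG(map$label_raster / 65535, path)
  invisible(path)
}

#' @rdname render_map
#' @param object a `prediction_map`.
#' @param ... unused.
#' @export
autoplot.prediction_map <- function(object, ...) {
  d <- dim(object$label_raster)
  df <- tibble(
    row = rep(seq_len(d[1L]), times = d[2L]),
    col = rep(seq_len(d[2L]), each = d[1L]),
    class = factor(as.vector(object$label_raster))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey15", object$colour_table)
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "predicted class")
}
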