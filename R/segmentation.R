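#' Segment seeds from a greyscale band image
#'
#' Thresholds the image with Otsu's method (computed on the clipped
#' \[0, 1\] histogram), labels 8-connected foreground components and
#' discards components smaller than `min_area` pixels. Border-touching
#' objects are kept but flagged. Object ids follow raster-scan order of
#' each object's first pixel, so segmentation is deterministic.
#'
#' @param grey numeric matrix, e.g. from [select_segmentation_band()].
#' @param min_area smallest object kept, in pixels.
#' @param threshold optional manual threshold overriding Otsu.
#' @return An object of class `seed_segmentation`: list with `labels`
#'   (integer raster, 0 = background), `objects` (tibble: `object_id`,
#'   `area_px`, `centroid_row`, `centroid_col`, `on_border`) and
#'   `threshold`. A constant image yields zero objects.
#' @export
segment_seeds <- function(grey, min_area = 10, threshold = NULL) {
  if (!is.matrix(grey) || !is.numeric(grey)) {
    abort("`grey` must be a numeric matrix.")
  }
  if (any(!is.finite(grey))) abort("`grey` must be finite.")
  if (is.null(threshold)) {
    if (max(grey) - min(grey) < 1e-12) {
      # constant image: nothing to separate
      return(new_segmentation(matrix(0L, nrow(grey), ncol(grey)), NA_real_,
                              min_area))
    }
    clipped <- pmin(pmax(grey, 0), 1)
    threshold <- EBImage::otsu(EBImage::Image(clipped))
  }
  bw <- grey > threshold
  lab <- label_components8(bw)
  lab <- drop_small_components(lab, min_area)
  new_segmentation(lab, threshold, min_area)
}

new_segmentation <- function(labels, threshold, min_area) {
  ids <- sort(unique(labels[labels > 0L]))
  objs <- purrr::map_dfr(ids, function(id) {
    px <- which(labels == id)
    rr <- (px - 1L) %% nrow(labels) + 1L
    cc <- (px - 1L) %/% nrow(labels) + 1L
    tibble(
      object_id = id,
      area_px = length(px),
      centroid_row = mean(rr),
      centroid_col = mean(cc),
      on_border = any(rr == 1L | rr == nrow(labels) |
                        cc == 1L | cc == ncol(labels))
    )
  })
  if (length(ids) == 0L) {
    objs <- tibble(object_id = integer(), area_px = integer(),
                   centroid_row = numeric(), centroid_col = numeric(),
                   on_border = logical())
  }
  structure(
    list(labels = labels, objects = objs, threshold = threshold,
         min_area = min_area),
    class = "seed_segmentation"
  )
}

#' @export
print.seed_segmentation <- function(x, ...) {
  cat(sprintf("<seed_segmentation> %d objects (threshold %.4g, min_area %d)\n",
              nrow(x$objects), x$threshold, x$min_area))
  invisible(x)
}

#' @rdname segment_seeds
#' @param seg a `seed_segmentation`.
#' @param object_id id of the object to extract.
#' @return `seed_mask()` returns the object's full-size logical mask.
#' @export
seed_mask <- function(seg, object_id) {
  m <- seg$labels == object_id
  if (!any(m)) abort(sprintf("no object with id %d.", object_id))
  m
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so components
# that only touch diagonally are merged afterwards with a union-find pass.
label_components8 <- function(bw) {
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(bw), ncol(bw))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    dr <- shift[1L]
    dc <- shift[2L]
    rs <- seq_len(nr - 1L)
    cs <- if (dc == 1L) seq_len(nc - 1L) else 2L:nc
    a <- lab[rs, cs, drop = FALSE]
    b <- lab[rs + dr, cs + dc, drop = FALSE]
    touching <- which(a > 0L & b > 0L & a != b)
    for (i in touching) {
      ra <- find(a[i])
      rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  lab[lab > 0L] <- roots[lab[lab > 0L]]
  relabel_scan_order(lab)
}

# consecutive ids ordered by each object's first pixel in column-major scan
relabel_scan_order <- function(lab) {
  pos <- which(lab > 0L)
  if (length(pos) == 0L) return(lab)
  first <- tapply(pos, lab[pos], min)
  old <- as.integer(names(first))[order(first)]
  map <- integer(max(lab))
  map[old] <- seq_along(old)
  lab[pos] <- map[lab[pos]]
  lab
}

drop_small_components <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_area)
  if (length(small)) {
    lab[lab %in% small] <- 0L
    lab <- relabel_scan_order(lab)
  }
  lab
}
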