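#' Pixel-based seed morphometry
#'
#' Computes the four shape features used for seed phenotyping:
#' \describe{
#'   \item{area_px}{total number of object pixels (contour included)}
#'   \item{perimeter_px}{number of contour pixels, i.e. object pixels with
#'     at least one 4-adjacent background pixel or lying on the image
#'     border}
#'   \item{length_px, width_px}{full major/minor axis lengths of the
#'     ellipse with the same second central moments as the pixel blob
#'     (each pixel contributes its unit-square variance of 1/12)}
#' }
#'
#' @param mask logical (or 0/1) matrix of one seed.
#' @return A one-row tibble: `area_px`, `perimeter_px`, `length_px`,
#'   `width_px`, `orientation` (radians, major axis vs. column axis),
#'   `centroid_row`, `centroid_col`.
#' @examples
#' compute_morphology(matrix(TRUE, 3, 3))  # area 9, perimeter 8
#' @export
compute_morphology <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  mask <- mask != 0
  if (!any(mask)) abort("`mask` is empty.")
  area <- sum(mask)

  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]
  down <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  contour <- inner & !(up & down & left & right)
  perimeter <- sum(contour)

  px <- which(mask)
  rr <- (px - 1L) %% nr + 1L
  cc <- (px - 1L) %/% nr + 1L
  mu_r <- mean(rr)
  mu_c <- mean(cc)
  # population second central moments + per-pixel square term
  srr <- mean((rr - mu_r)^2) + 1 / 12
  scc <- mean((cc - mu_c)^2) + 1 / 12
  src <- mean((rr - mu_r) * (cc - mu_c))
  tr <- srr + scc
  det <- srr * scc - src^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  orientation <- 0.5 * atan2(2 * src, scc - srr)

  tibble(
    area_px = area,
    perimeter_px = perimeter,
    length_px = 4 * sqrt(l1),
    width_px = 4 * sqrt(pmax(l2, 0)),
    orientation = orientation,
    centroid_row = mu_r,
    centroid_col = mu_c
  )
}

#' Morphometry of every segmented seed
#'
#' @param seg a [segment_seeds()] result.
#' @return A tibble with one row per object: the [compute_morphology()]
#'   features plus `object_id` and `on_border`.
#' @export
seed_morphology <- function(seg) {
  if (!inherits(seg, "seed_segmentation")) {
    abort("`seg` must be a seed_segmentation.")
  }
  if (nrow(seg$objects) == 0L) {
    return(tibble(object_id = integer(), area_px = integer(),
                  perimeter_px = integer(), length_px = numeric(),
                  width_px = numeric(), orientation = numeric(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  on_border = logical()))
  }
  nr <- nrow(seg$labels)
  feats <- purrr::map_dfr(seg$objects$object_id, function(id) {
    px <- which(seg$labels == id)
    rr <- (px - 1L) %% nr + 1L
    cc <- (px - 1L) %/% nr + 1L
    box <- matrix(FALSE, diff(range(rr)) + 1L, diff(range(cc)) + 1L)
    box[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
    m <- compute_morphology(box)
    m$centroid_row <- m$centroid_row + min(rr) - 1
    m$centroid_col <- m$centroid_col + min(cc) - 1
    m$object_id <- id
    m
  })
  dplyr::left_join(feats, seg$objects[, c("object_id", "on_border")],
                   by = "object_id")[
    , c("object_id", "area_px", "perimeter_px", "length_px", "width_px",
        "orientation", "centroid_row", "centroid_col", "on_border")
  ]
}

#' Thousand-grain weight from 100-seed sample masses
#'
#' Seed mass is measured on independent 100-seed samples (conventionally
#' five); thousand-grain weight is ten times the mean 100-seed mass.
#'
#' @param masses positive masses in grams of 100-seed samples.
#' @return A one-row tibble: `n_samples`, `mean_mass_g` (mean 100-seed
#'   mass), `tgw_g`.
#' @examples
#' tgw_from_samples(c(2.40, 2.45, 2.50, 2.55, 2.60))$tgw_g  # 25
#' @export
tgw_from_samples <- function(masses) {
  if (length(masses) < 1L || !is.numeric(masses)) {
    abort("`masses` must hold at least one mass.")
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    abort("all `masses` must be positive and finite.")
  }
  tibble(
    n_samples = length(masses),
    mean_mass_g = mean(masses),
    tgw_g = 10 * mean(masses)
  )
}

#' Percent increase of a mutant mean over the wild-type mean
#'
#' `100 * (mutant_mean - wt_mean) / wt_mean`, reported to one decimal
#' (half-up), the convention used for trait-increase summaries such as
#' thousand-grain weight gains.
#'
#' @param mutant_mean,wt_mean group means; `wt_mean` must be positive.
#' @return Percent increase rounded to one decimal place (vectorised).
#' @examples
#' percent_increase(25.99, 24.56)  # 5.8
#' @export
percent_increase <- function(mutant_mean, wt_mean) {
  if (any(!is.finite(wt_mean)) || any(wt_mean <= 0)) {
    abort("`wt_mean` must be positive.")
  }
  round_half_up(100 * (mutant_mean - wt_mean) / wt_mean, 1)
}
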