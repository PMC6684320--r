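#' Globally optimal nucleus-Golgi assignment
#'
#' Pairs each nucleus with a Golgi centroid by minimizing the total Euclidean
#' distance over all one-to-one assignments (linear assignment / Hungarian
#' solution, not greedy nearest-neighbour: greedy can be beaten on simple
#' configurations). Rectangular inputs are allowed; the surplus centroids end
#' up unmatched. Pairs farther apart than `max_distance_um` are dissolved
#' afterwards into the unmatched sets, which guards against implausible
#' long-range matches when one organelle failed to segment.
#'
#' @param nuclei,golgi two-column matrices (x, y in micrometres) of centroids.
#' @param max_distance_um pairs farther than this are dissolved (default 30).
#' @return list with `pairs` (data.frame: `nucleus`, `golgi` row indices and
#'   `distance_um`), `unmatched_nuclei`, `unmatched_golgi` (integer indices).
#' @export
assign_golgi <- function(nuclei, golgi, max_distance_um = 30) {
  nuc <- matrix(as.numeric(as.matrix(nuclei)), ncol = 2)
  gol <- matrix(as.numeric(as.matrix(golgi)), ncol = 2)
  if (nrow(nuc) == 0L || nrow(gol) == 0L)
    stop("both centroid lists must be non-empty", call. = FALSE)
  D <- sqrt(outer(nuc[, 1], gol[, 1], "-")^2 +
            outer(nuc[, 2], gol[, 2], "-")^2)
  if (nrow(D) <= ncol(D)) {
    sol <- as.integer(clue::solve_LSAP(D))
    pairs <- data.frame(nucleus = seq_len(nrow(D)), golgi = sol)
  } else {
    sol <- as.integer(clue::solve_LSAP(t(D)))
    pairs <- data.frame(nucleus = sol, golgi = seq_len(ncol(D)))
  }
  pairs$distance_um <- D[cbind(pairs$nucleus, pairs$golgi)]
  keep <- pairs$distance_um <= max_distance_um
  dropped <- pairs[!keep, , drop = FALSE]
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$nucleus), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_nuclei = sort(c(setdiff(seq_len(nrow(nuc)), c(pairs$nucleus, dropped$nucleus)),
                                 dropped$nucleus)),
       unmatched_golgi = sort(c(setdiff(seq_len(nrow(gol)), c(pairs$golgi, dropped$golgi)),
                                dropped$golgi)))
}

#' Centroids of segmented organelles
#'
#' Thresholds a single-channel image (Golgi or nuclear staining), labels
#' connected components, removes components below a minimum area and returns
#' centroids in physical units. Pixel `(row, col)` maps to coordinates
#' `x = (col - 1) * pixel_size_um`, `y = (row - 1) * pixel_size_um`
#' (image frame: origin top-left, y increasing downward).
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param pixel_size_um physical pixel size; required.
#' @param min_area_px minimum component area in pixels (default 9).
#' @param threshold `"otsu"` (default) or a numeric cutoff on intensity.
#' @return data.frame with `label`, `x_um`, `y_um`, `area_px`, ordered by
#'   label (raster scan order). Empty segmentation returns zero rows with a
#'   warning.
#' @export
segment_centroids <- function(image, pixel_size_um, min_area_px = 9,
                              threshold = "otsu") {
  if (missing(pixel_size_um) || is.null(pixel_size_um))
    stop("'pixel_size_um' is required (no pixel size in input)", call. = FALSE)
  .assert_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  img <- as.matrix(image)
  mask <- segment_mask(img, threshold = threshold, min_object_px = min_area_px)
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0L) {  # segment_mask already warned
    return(data.frame(label = integer(), x_um = numeric(), y_um = numeric(),
                      area_px = integer()))
  }
  ij <- which(lab > 0, arr.ind = TRUE)
  l <- lab[ij]
  area <- tabulate(l, nbins = nlab)
  ybar <- tapply(ij[, 1], l, mean)
  xbar <- tapply(ij[, 2], l, mean)
  data.frame(label = seq_len(nlab),
             x_um = (as.numeric(xbar) - 1) * pixel_size_um,
             y_um = (as.numeric(ybar) - 1) * pixel_size_um,
             area_px = area)
}
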