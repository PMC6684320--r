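#' Segment a channel into a binary mask
#'
#' Global Otsu threshold by default; a fixed numeric cutoff or a local
#' adaptive threshold are available. Objects smaller than `min_object_px`
#' connected pixels are removed.
#'
#' @param image numeric matrix.
#' @param threshold `"otsu"` (default), `"adaptive"`, or a numeric intensity
#'   cutoff.
#' @param min_object_px minimum connected-component size kept (default 9).
#' @param adaptive_width window half-width for the adaptive method (px).
#' @return Binary (0/1) integer matrix of the same shape. A constant image
#'   is degenerate and yields an empty mask with a warning.
#' @export
segment_mask <- function(image, threshold = "otsu", min_object_px = 9,
                         adaptive_width = 15) {
  img <- as.matrix(image)
  rng <- range(img, finite = TRUE)
  if (is.numeric(threshold)) {
    mask <- img > threshold
  } else if (identical(threshold, "otsu")) {
    if (rng[1] == rng[2]) {
      warning("constant image: degenerate segmentation, returning empty mask")
      return(matrix(0L, nrow(img), ncol(img)))
    }
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > th
  } else if (identical(threshold, "adaptive")) {
    if (rng[1] == rng[2]) {
      warning("constant image: degenerate segmentation, returning empty mask")
      return(matrix(0L, nrow(img), ncol(img)))
    }
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    mask <- EBImage::thresh(EBImage::Image(norm),
                            w = adaptive_width, h = adaptive_width,
                            offset = 0.01) > 0
    mask <- matrix(as.logical(mask), nrow(img), ncol(img))
  } else stop("unknown threshold method")
  if (!any(mask)) {
    warning("empty mask after thresholding")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  if (min_object_px > 1) {
    lab <- EBImage::bwlabel(mask)
    if (max(lab) > 0) {
      area <- tabulate(lab[lab > 0], nbins = max(lab))
      mask <- matrix(area[ifelse(lab > 0, lab, NA)] >= min_object_px &
                       lab > 0, nrow(img), ncol(img))
      mask[is.na(mask)] <- FALSE
    }
  }
  matrix(as.integer(mask), nrow(img), ncol(img))
}

#' Object-based overlap fraction of two binary masks
#'
#' Object-based co-localization: both channels are segmented into binary
#' masks and the fraction of overlapping pixels is reported as a percentage,
#' \eqn{100 |A \cap B| / |D|}, where the denominator mask `D` is the query
#' channel by default (e.g. percent of the vinculin mask overlapping
#' VE-cadherin), the reference channel, or the union.
#'
#' @param mask_a query-channel binary mask (matrix of 0/1 or logical).
#' @param mask_b reference-channel binary mask, same shape.
#' @param denominator `"query"` (mask_a, default), `"reference"` (mask_b) or
#'   `"union"`.
#' @return list with `overlap_percent`, `n_pixels_a`, `n_pixels_b`,
#'   `n_overlap`, `denominator`.
#' @export
overlap_fraction <- function(mask_a, mask_b,
                             denominator = c("query", "reference", "union")) {
  denominator <- match.arg(denominator)
  a <- as.matrix(mask_a) > 0
  b <- as.matrix(mask_b) > 0
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  inter <- sum(a & b)
  den <- switch(denominator, query = sum(a), reference = sum(b),
                union = sum(a | b))
  if (den == 0L) stop("empty denominator mask", call. = FALSE)
  list(overlap_percent = 100 * inter / den,
       n_pixels_a = sum(a), n_pixels_b = sum(b), n_overlap = inter,
       denominator = denominator)
}

#' Co-localization time course
#'
#' Applies [segment_mask()] + [overlap_fraction()] with identical settings
#' to an image-pair series (e.g. vinculin / VE-cadherin after a calcium
#' switch) and tabulates overlap percentage against time. A missing
#' timepoint (NULL entry) is flagged, not interpolated.
#'
#' @param images_a,images_b lists of images (query and reference channel),
#'   one per timepoint; `NULL` entries mark missing timepoints.
#' @param timepoints_min numeric vector of timepoints (minutes).
#' @param denominator passed to [overlap_fraction()].
#' @param threshold,min_object_px passed to [segment_mask()].
#' @return data.frame with `time_min`, `overlap_percent`, `n_pixels_a`,
#'   `n_pixels_b`, `n_overlap`, `missing`.
#' @export
coloc_timecourse <- function(images_a, images_b, timepoints_min,
                             denominator = "query", threshold = "otsu",
                             min_object_px = 9) {
  if (length(timepoints_min) < 2L) stop("need >= 2 timepoints")
  stopifnot(length(images_a) == length(timepoints_min),
            length(images_b) == length(timepoints_min))
  shp <- NULL
  rows <- lapply(seq_along(timepoints_min), function(i) {
    if (is.null(images_a[[i]]) || is.null(images_b[[i]]))
      return(data.frame(time_min = timepoints_min[i],
                        overlap_percent = NA_real_, n_pixels_a = NA_integer_,
                        n_pixels_b = NA_integer_, n_overlap = NA_integer_,
                        missing = TRUE))
    d <- dim(as.matrix(images_a[[i]]))
    if (is.null(shp)) shp <<- d
    if (!all(d == shp)) stop("inconsistent image shapes across timepoints")
    ma <- segment_mask(images_a[[i]], threshold, min_object_px)
    mb <- segment_mask(images_b[[i]], threshold, min_object_px)
    ov <- overlap_fraction(ma, mb, denominator)
    data.frame(time_min = timepoints_min[i],
               overlap_percent = ov$overlap_percent,
               n_pixels_a = ov$n_pixels_a, n_pixels_b = ov$n_pixels_b,
               n_overlap = ov$n_overlap, missing = FALSE)
  })
  do.call(rbind, rows)
}
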