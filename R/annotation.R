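# Tallies of manually annotated categorical measurements: junction
# morphology perimeter fractions and stress-fiber-junction connections.
# Counting only; no automated classifier is attempted because the
# morphological classes (linear / serrated / reticular) are defined by
# visual criteria.

#' Junction-morphology perimeter fractions
#'
#' Each cell's perimeter is manually partitioned into labeled segments of
#' class linear, serrated or reticular; this tallies the length-weighted
#' percentage of perimeter per class and the group mean +/- SD. If
#' `start_um` / `end_um` columns are present, overlapping segments within a
#' cell are an error.
#'
#' @param annotations data.frame with columns `cell_id`, `class` (one of
#'   `"linear"`, `"serrated"`, `"reticular"`) and `length_um`; optional
#'   `start_um`, `end_um`.
#' @return list with `per_cell` (data.frame: `cell_id`, one percentage
#'   column per class, summing to 100) and `summary` (per-class mean, SD,
#'   n of the per-cell percentages).
#' @export
perimeter_fractions <- function(annotations) {
  classes <- c("linear", "serrated", "reticular")
  stopifnot(all(c("cell_id", "class", "length_um") %in% names(annotations)))
  if (nrow(annotations) < 1L) stop("need >= 1 annotated cell", call. = FALSE)
  if (!all(annotations$class %in% classes))
    stop("unknown junction class", call. = FALSE)
  if (any(annotations$length_um < 0)) stop("negative segment length")
  if (all(c("start_um", "end_um") %in% names(annotations))) {
    for (g in split(annotations, annotations$cell_id)) {
      o <- order(g$start_um)
      if (any(g$start_um[o][-1] < g$end_um[o][-nrow(g)] - 1e-9))
        stop("overlapping perimeter segments in cell ", g$cell_id[1],
             call. = FALSE)
    }
  }
  per_cell <- do.call(rbind, lapply(split(annotations, annotations$cell_id),
    function(g) {
      tot <- sum(g$length_um)
      if (tot <= 0) stop("cell with zero annotated perimeter")
      shares <- vapply(classes, function(cl)
        100 * sum(g$length_um[g$class == cl]) / tot, numeric(1))
      data.frame(cell_id = g$cell_id[1], t(shares))
    }))
  rownames(per_cell) <- NULL
  summary <- data.frame(
    class = classes,
    mean_percent = vapply(classes, function(cl) mean(per_cell[[cl]]),
                          numeric(1)),
    sd_percent = vapply(classes, function(cl)
      if (nrow(per_cell) > 1) sd(per_cell[[cl]]) else 0, numeric(1)),
    n_cells = nrow(per_cell))
  rownames(summary) <- NULL
  list(per_cell = per_cell, summary = summary)
}

#' Count stress fibers connected to junctions
#'
#' Counts manually marked actin stress fibers connected to VE-cadherin
#' positive cell-cell junctions, per image. Duplicate fiber ids within an
#' image collapse to one.
#'
#' @param annotations data.frame with columns `image_id` and `fiber_id`
#'   (may have zero rows).
#' @return list with `per_image` (data.frame: `image_id`, `n_fibers`) and
#'   `summary` (mean, SD, n of per-image counts).
#' @export
fiber_connection_count <- function(annotations) {
  stopifnot(all(c("image_id", "fiber_id") %in% names(annotations)))
  if (nrow(annotations) == 0L)
    return(list(per_image = data.frame(image_id = character(),
                                       n_fibers = integer()),
                summary = data.frame(mean_fibers = 0, sd_fibers = NA_real_,
                                     n_images = 0L)))
  per_image <- do.call(rbind, lapply(split(annotations, annotations$image_id),
    function(g) data.frame(image_id = g$image_id[1],
                           n_fibers = length(unique(g$fiber_id)))))
  rownames(per_image) <- NULL
  list(per_image = per_image,
       summary = data.frame(
         mean_fibers = mean(per_image$n_fibers),
         sd_fibers = if (nrow(per_image) > 1) sd(per_image$n_fibers)
                     else NA_real_,
         n_images = nrow(per_image)))
}
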