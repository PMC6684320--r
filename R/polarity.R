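#' Polarity index of an angular sample
#'
#' The polarity index (PI) is the length of the mean resultant vector of a
#' set of polarity angles:
#' \deqn{PI = \sqrt{\left(\frac{1}{N}\sum_i \cos\alpha_i\right)^2 +
#'                  \left(\frac{1}{N}\sum_i \sin\alpha_i\right)^2}}
#' It ranges from 1 (all cells share one polarity direction) to 0 (angles
#' uniform on the circle) and is used as the population-level measure of
#' collective polarization. The direction of the resultant is the mean
#' polarity angle.
#'
#' @param angles_deg numeric vector of polarity angles in degrees
#'   (any representatives; internally wrapped on the circle).
#' @return Object of class `polarity_index`: list with elements `pi`
#'   (in \[0, 1\]), `mean_angle_deg` (degrees in (-180, 180\]) and `n`.
#' @examples
#' polarity_index(c(0, 0, 0))$pi        # 1: fully polarized
#' polarity_index(c(0, 90, 180, 270))$pi  # 0: symmetric
#' polarity_index(c(0, 90))              # pi = sqrt(2)/2, mean 45 degrees
#' @export
polarity_index <- function(angles_deg) {
  if (length(angles_deg) < 1L)
    stop("polarity_index() needs at least one angle", call. = FALSE)
  if (!all(is.finite(angles_deg)))
    stop("angles must be finite", call. = FALSE)
  a <- deg2rad(angles_deg)
  C <- mean(cos(a)); S <- mean(sin(a))
  r <- min(sqrt(C^2 + S^2), 1)
  structure(
    list(pi = r,
         mean_angle_deg = wrap_deg(rad2deg(atan2(S, C))),
         n = length(a)),
    class = "polarity_index")
}

#' @export
print.polarity_index <- function(x, ...) {
  cat(sprintf("PI = %.3f  (mean angle %.1f deg, n = %d)\n",
              x$pi, x$mean_angle_deg, x$n))
  invisible(x)
}

#' Polarity angle of a cell relative to the free edge
#'
#' The polarity axis of a cell is the vector drawn from the nucleus centroid
#' to the Golgi centroid. Its polarity angle is the signed angle between that
#' vector and the inward normal (pointing into the free space) of the nearest
#' edge segment, so 0 degrees means the cell points straight at the wound /
#' sprouting front, 180 degrees means it points straight away from it.
#'
#' @param nucleus_xy,golgi_xy two-column matrices (or length-2 vectors) of
#'   centroid coordinates in micrometres; rows are paired cells.
#' @param edge an [edge_reference()].
#' @return Numeric vector of angles in degrees in (-180, 180\]; `NA` (with a
#'   warning) for cells whose polarity vector has zero length.
#' @export
polarity_angle <- function(nucleus_xy, golgi_xy, edge) {
  nuc <- matrix(as.numeric(as.matrix(nucleus_xy)), ncol = 2)
  gol <- matrix(as.numeric(as.matrix(golgi_xy)), ncol = 2)
  if (nrow(nuc) != nrow(gol))
    stop("nucleus and golgi coordinate sets differ in length", call. = FALSE)
  v <- gol - nuc
  zero <- rowSums(v^2) == 0
  if (any(zero))
    warning(sprintf("%d cell(s) with zero-length polarity vector flagged NA",
                    sum(zero)))
  prj <- edge_project(nuc, edge)
  dotp <- prj$normal_x * v[, 1] + prj$normal_y * v[, 2]
  crossp <- prj$normal_y * v[, 1] - prj$normal_x * v[, 2]
  ang <- wrap_deg(rad2deg(atan2(crossp, dotp)))
  ang[zero] <- NA_real_
  ang
}

#' Build per-cell polarity records from paired centroids
#'
#' Convenience wrapper combining [polarity_angle()] and [distance_to_edge()]
#' into the per-cell table the downstream profile and row-classification
#' steps consume.
#'
#' @inheritParams polarity_angle
#' @param cell_id optional identifiers (default sequential).
#' @return data.frame with columns `cell_id`, `nucleus_x_um`, `nucleus_y_um`,
#'   `golgi_x_um`, `golgi_y_um`, `alpha_deg`, `distance_um`.
#' @export
polarity_records <- function(nucleus_xy, golgi_xy, edge, cell_id = NULL) {
  nuc <- matrix(as.numeric(as.matrix(nucleus_xy)), ncol = 2)
  gol <- matrix(as.numeric(as.matrix(golgi_xy)), ncol = 2)
  if (is.null(cell_id)) cell_id <- seq_len(nrow(nuc))
  data.frame(
    cell_id = cell_id,
    nucleus_x_um = nuc[, 1], nucleus_y_um = nuc[, 2],
    golgi_x_um = gol[, 1], golgi_y_um = gol[, 2],
    alpha_deg = polarity_angle(nuc, gol, edge),
    distance_um = distance_to_edge(nuc, edge))
}

#' Distance-binned polarity profile
#'
#' Computes the polarity index in consecutive distance bins from the free
#' edge into the monolayer (default 50 um wide), the spatial profile used to
#' read how deep collective polarization reaches. Bins are half-open
#' `[k*w, (k+1)*w)` starting at 0 at the edge, so every cell falls in exactly
#' one bin; a cell exactly on a bin boundary belongs to the farther bin.
#'
#' @param records data.frame with columns `alpha_deg` and `distance_um`
#'   (e.g. from [polarity_records()]); rows with `NA` angle are dropped.
#' @param bin_width_um bin width in micrometres (default 50).
#' @param max_distance_um optional truncation; default covers all cells.
#' @return data.frame of class `polarity_profile` with columns
#'   `bin_start_um`, `bin_end_um`, `n`, `pi`, `mean_angle_deg`. Bins with no
#'   cells carry `NA` for `pi` and `mean_angle_deg`.
#' @export
bin_pi_by_distance <- function(records, bin_width_um = 50,
                               max_distance_um = NULL) {
  .assert_number(bin_width_um, "bin_width_um", positive = TRUE)
  rec <- records[!is.na(records$alpha_deg), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records with defined polarity angle")
  if (any(rec$distance_um < 0)) stop("negative distance_um")
  nbin <- if (is.null(max_distance_um)) {
    floor(max(rec$distance_um) / bin_width_um) + 1L  # cover every cell
  } else {
    max(1L, as.integer(ceiling(max_distance_um / bin_width_um - 1e-9)))
  }
  idx <- floor(rec$distance_um / bin_width_um) + 1L
  rec <- rec[idx <= nbin, , drop = FALSE]   # cells beyond the range are dropped
  idx <- idx[idx <= nbin]
  out <- data.frame(
    bin_start_um = (seq_len(nbin) - 1L) * bin_width_um,
    bin_end_um = seq_len(nbin) * bin_width_um,
    n = 0L, pi = NA_real_, mean_angle_deg = NA_real_)
  for (k in seq_len(nbin)) {
    a <- rec$alpha_deg[idx == k]
    out$n[k] <- length(a)
    if (length(a) > 0L) {
      p <- polarity_index(a)
      out$pi[k] <- p$pi
      out$mean_angle_deg[k] <- p$mean_angle_deg
    }
  }
  class(out) <- c("polarity_profile", "data.frame")
  out
}

#' Uncoordination threshold from per-bin polarity indices
#'
#' Even a fully randomized monolayer shows PI > 0 because the free-space /
#' monolayer interface geometrically biases polarity near the edge. The
#' uncoordination threshold is therefore derived empirically from a
#' junction-disrupted (uncoordinated) reference condition: pool the per-bin
#' PIs of its profiles, exclude the first bin (leader cells are strongly
#' edge-biased), and take mean + 1 sample SD. Profiles whose per-bin PI stays
#' below this value are called uncoordinated.
#'
#' With the published reference summary (per-bin PI 0.1 +/- 0.04 in
#' alpha-catenin-depleted monolayers) the rule gives a threshold of 0.14.
#'
#' @param profiles a `polarity_profile`, a list of them (one per image), or
#'   directly a numeric vector of pooled per-bin PIs.
#' @param exclude_first_bin drop the bin starting at 0 um from each profile
#'   (default TRUE, matching the exclusion of the edge-biased first row).
#' @param n_sd number of SDs above the mean (default 1).
#' @param mode `"pooled"` (default): one mean/SD over all bins of all images;
#'   `"per_image"`: apply the rule within each image and average the
#'   resulting thresholds.
#' @return Threshold PI (single number).
#' @examples
#' derive_threshold(c(0.06, 0.14, 0.10), exclude_first_bin = FALSE)  # 0.14
#' @export
derive_threshold <- function(profiles, exclude_first_bin = TRUE, n_sd = 1,
                             mode = c("pooled", "per_image")) {
  mode <- match.arg(mode)
  if (is.numeric(profiles)) {
    pis <- list(profiles)
  } else {
    if (inherits(profiles, "polarity_profile")) profiles <- list(profiles)
    pis <- lapply(profiles, function(p) {
      stopifnot(inherits(p, "polarity_profile"))
      keep <- !is.na(p$pi)
      if (exclude_first_bin) keep <- keep & p$bin_start_um > 0
      p$pi[keep]
    })
  }
  if (mode == "per_image") {
    th <- vapply(pis, function(v) {
      if (length(v) < 2L) stop("need >= 2 bins per image for per-image mode")
      mean(v) + n_sd * sd(v)
    }, numeric(1))
    return(mean(th))
  }
  v <- unlist(pis)
  if (length(v) < 2L)
    stop("need >= 2 contributing bins after exclusion", call. = FALSE)
  mean(v) + n_sd * sd(v)
}

#' Angular histogram over equal circular bins
#'
#' @param angles_deg angles in degrees.
#' @param n_bins number of equal bins covering 360 degrees (default 24,
#'   i.e. 15-degree bins).
#' @return data.frame with `bin_center_deg`, `bin_start_deg`, `bin_end_deg`
#'   and `count`; counts sum to `length(angles_deg)`. Bins tile
#'   \[-180, 180) half-open, so the first and last bins are circular
#'   neighbours.
#' @export
angular_histogram <- function(angles_deg, n_bins = 24) {
  if (length(angles_deg) < 1L) stop("need at least one angle")
  w <- 360 / n_bins
  a <- wrap_deg(angles_deg)
  a[a == 180] <- -180           # fold onto [-180, 180) for binning
  idx <- floor((a + 180) / w) + 1L
  idx[idx > n_bins] <- n_bins   # guard against fp roundoff at +180
  counts <- tabulate(idx, nbins = n_bins)
  start <- -180 + (seq_len(n_bins) - 1L) * w
  data.frame(bin_center_deg = start + w / 2,
             bin_start_deg = start, bin_end_deg = start + w,
             count = counts)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that polarity angles are uniformly distributed
#' on the circle against a unimodal alternative. The statistic is
#' `Z = n * PI^2`; the p-value uses the standard series approximation
#' (Greenwood & Durand / Zar).
#'
#' @param angles_deg angles in degrees, `n >= 5`.
#' @return list with `statistic` (Z), `pi`, `n` and `p_value`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 5L) stop("rayleigh_test() needs n >= 5", call. = FALSE)
  r <- polarity_index(angles_deg)$pi
  R <- n * r
  Z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(statistic = Z, pi = r, n = n, p_value = min(max(p, 0), 1))
}
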