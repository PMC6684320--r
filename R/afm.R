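#' Parse a single-cell force-spectroscopy curve
#'
#' Builds a `force_curve` from a long-format table with one row per sample
#' and a segment label. Segments are sorted by separation; non-monotone
#' duplicated separations are averaged with a warning.
#'
#' @param table data.frame with columns `segment` (`"approach"` /
#'   `"retract"`), `separation_um`, `force_pN`, and optionally `curve_id`.
#' @param contact_force_pN,contact_time_s optional metadata (defaults: the
#'   300 pN applied contact force and 5 s contact time used in the cell-cell
#'   adhesion protocol).
#' @return Object of class `force_curve`: list with `approach`, `retract`
#'   (data.frames `separation_um`, `force_pN`) and `metadata`.
#' @export
parse_curve <- function(table, contact_force_pN = 300, contact_time_s = 5) {
  need <- c("segment", "separation_um", "force_pN")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  segs <- lapply(c("approach", "retract"), function(s) {
    g <- table[table$segment == s, , drop = FALSE]
    if (nrow(g) == 0L) stop("missing segment: ", s, call. = FALSE)
    g <- g[order(g$separation_um), , drop = FALSE]
    if (anyDuplicated(g$separation_um)) {
      warning("non-monotone separation in ", s, " segment: averaging duplicates")
      f <- tapply(g$force_pN, g$separation_um, mean)
      g <- data.frame(separation_um = as.numeric(names(f)),
                      force_pN = as.numeric(f))
    }
    if (!all(is.finite(g$force_pN))) stop("non-finite forces", call. = FALSE)
    data.frame(separation_um = g$separation_um, force_pN = g$force_pN)
  })
  structure(list(approach = segs[[1]], retract = segs[[2]],
                 metadata = list(
                   curve_id = if ("curve_id" %in% names(table))
                     table$curve_id[1] else NA,
                   contact_force_pN = contact_force_pN,
                   contact_time_s = contact_time_s)),
            class = "force_curve")
}

# baseline = mean force over the far-separation fraction of a segment
.baseline_correct <- function(seg, baseline_frac = 0.1) {
  s <- seg$separation_um
  cut <- max(s) - baseline_frac * (max(s) - min(s))
  base <- mean(seg$force_pN[s >= cut])
  seg$force_pN <- seg$force_pN - base
  seg
}

#' Detachment work from a force curve
#'
#' The work (energy) needed to fully separate two adhered cells is the area
#' enclosed between the baseline-corrected approach and retraction traces
#' over the detachment region, integrated by the trapezoid rule and
#' converted from pN um to femtojoules (1 pN um = 1e-3 fJ). Each segment is
#' baseline-corrected independently using the mean force over its
#' far-separation 10%.
#'
#' The default `"hysteresis"` mode integrates the positive part of
#' (approach - retract); `"retract"` mode integrates only the negative
#' retract force against its baseline.
#'
#' @param curve a `force_curve`.
#' @param mode `"hysteresis"` (default) or `"retract"`.
#' @param baseline_frac far-separation fraction used for the baseline
#'   (default 0.1).
#' @return list with `work_fJ`, `flag` (`"no_adhesion_well"` when the
#'   retract trace never drops below baseline, else `"ok"`), and `mode`.
#' @export
detachment_work <- function(curve, mode = c("hysteresis", "retract"),
                            baseline_frac = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "force_curve"))
  app <- .baseline_correct(curve$approach, baseline_frac)
  ret <- .baseline_correct(curve$retract, baseline_frac)
  lo <- max(min(app$separation_um), min(ret$separation_um))
  hi <- min(max(app$separation_um), max(ret$separation_um))
  if (hi <= lo) stop("segments share no separation range", call. = FALSE)
  grid <- sort(unique(c(app$separation_um, ret$separation_um)))
  grid <- grid[grid >= lo & grid <= hi]
  fa <- approx(app$separation_um, app$force_pN, grid)$y
  fr <- approx(ret$separation_um, ret$force_pN, grid)$y
  flag <- if (min(fr) >= 0) "no_adhesion_well" else "ok"
  integrand <- if (mode == "hysteresis") pmax(fa - fr, 0) else pmax(-fr, 0)
  work_pN_um <- .trapz(grid, integrand)
  list(work_fJ = work_pN_um * 1e-3, flag = flag, mode = mode)
}

#' Maximum detachment force
#'
#' The magnitude of the most negative baseline-corrected retract force, i.e.
#' the total force needed to separate the two cells, read from the y axis of
#' the force-distance curve.
#'
#' @inheritParams detachment_work
#' @return Force in pN (>= 0; 0 when there is no adhesion well).
#' @export
max_detachment_force <- function(curve, baseline_frac = 0.1) {
  stopifnot(inherits(curve, "force_curve"))
  ret <- .baseline_correct(curve$retract, baseline_frac)
  max(0, -min(ret$force_pN))
}

#' Cadherin-dependent fraction of detachment events
#'
#' Fraction (percent) of cell-cell detachment events with maximum detachment
#' force strictly above the threshold; 150 pN separates cadherin-dependent
#' from cadherin-independent interactions (calibrated on VE-cadherin
#' knockdown histograms). Strict inequality: an event at exactly the
#' threshold does not count.
#'
#' @param forces_pN numeric vector of maximum detachment forces (pN).
#' @param threshold_pN threshold (default 150).
#' @return Percent of events above threshold.
#' @export
cadherin_fraction <- function(forces_pN, threshold_pN = 150) {
  if (length(forces_pN) < 1L) stop("empty force list", call. = FALSE)
  100 * mean(forces_pN > threshold_pN)
}

#' Detachment-force histogram
#'
#' @param forces_pN numeric vector of maximum detachment forces (pN).
#' @param bin_width_pN bin width (default 25 pN).
#' @return data.frame with `bin_start_pN`, `bin_end_pN`, `count`.
#' @export
force_histogram <- function(forces_pN, bin_width_pN = 25) {
  if (length(forces_pN) < 1L) stop("empty force list", call. = FALSE)
  nbin <- max(1L, ceiling(max(forces_pN) / bin_width_pN + 1e-9))
  idx <- pmin(floor(forces_pN / bin_width_pN) + 1L, nbin)
  data.frame(bin_start_pN = (seq_len(nbin) - 1L) * bin_width_pN,
             bin_end_pN = seq_len(nbin) * bin_width_pN,
             count = tabulate(idx, nbins = nbin))
}
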