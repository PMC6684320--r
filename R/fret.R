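#' FRET efficiency by acceptor photobleaching
#'
#' In an acceptor-photobleaching experiment the donor is dequenched when the
#' acceptor is destroyed, so FRET efficiency is read from the fractional
#' rise of donor intensity in the bleached region of interest:
#' \deqn{EF = (I_{post} - I_{pre}) / I_{post}}
#' where the intensities are ROI means of the donor channel after and before
#' bleaching. A Gaussian prefilter (sd 0.75 px) is applied to both images
#' before measuring.
#'
#' @param donor_pre,donor_post donor-channel images (matrices, same shape).
#' @param roi logical mask (same shape) or two-column matrix of pixel
#'   indices; must be non-empty.
#' @param gaussian_sd sd of the Gaussian prefilter in pixels (default 0.75);
#'   0 disables filtering.
#' @return list with `ef`, `i_pre`, `i_post`, and `flag` (`"donor_loss"`
#'   when EF < 0, otherwise `"ok"`). A non-positive post-bleach ROI mean is
#'   an error.
#' @export
fret_efficiency <- function(donor_pre, donor_post, roi, gaussian_sd = 0.75) {
  pre <- as.matrix(donor_pre); post <- as.matrix(donor_post)
  if (!all(dim(pre) == dim(post))) stop("image shapes differ", call. = FALSE)
  m <- .roi_mask(roi, dim(pre))
  if (!any(m)) stop("empty ROI", call. = FALSE)
  if (gaussian_sd > 0) {
    pre <- .gblur(pre, gaussian_sd)
    post <- .gblur(post, gaussian_sd)
  }
  i_pre <- mean(pre[m]); i_post <- mean(post[m])
  if (i_post <= 0) stop("non-positive post-bleach ROI mean", call. = FALSE)
  ef <- (i_post - i_pre) / i_post
  list(ef = ef, i_pre = i_pre, i_post = i_post,
       flag = if (ef < 0) "donor_loss" else "ok")
}

.roi_mask <- function(roi, dims) {
  if (is.logical(roi)) {
    if (!all(dim(roi) == dims)) stop("ROI shape differs from image")
    return(roi)
  }
  m <- matrix(FALSE, dims[1], dims[2])
  m[as.matrix(roi)] <- TRUE
  m
}

# Gaussian blur via EBImage; brush size covers +-3 sd
.gblur <- function(img, sigma) {
  out <- EBImage::gblur(EBImage::Image(img), sigma = sigma)
  matrix(EBImage::imageData(out), nrow(img), ncol(img))
}

#' Pixelwise ratiometric biosensor map
#'
#' FRET/donor ratio inside a cell mask; pixels where the donor is zero are
#' excluded (NA), never returned as infinities.
#'
#' @param donor_img,fret_img same-shape matrices.
#' @param cell_mask logical mask (same shape), non-empty.
#' @return Matrix of ratios, NA outside the mask and at zero-donor pixels.
#' @export
ratio_map <- function(donor_img, fret_img, cell_mask) {
  d <- as.matrix(donor_img); f <- as.matrix(fret_img)
  if (!all(dim(d) == dim(f))) stop("image shapes differ", call. = FALSE)
  m <- as.matrix(cell_mask) > 0
  if (!any(m)) stop("empty cell mask", call. = FALSE)
  out <- matrix(NA_real_, nrow(d), ncol(d))
  ok <- m & d != 0
  out[ok] <- f[ok] / d[ok]
  out
}

#' Merge peak frames into activation events (3-frame rule)
#'
#' Maxima found within `merge_window` frames of each other are assumed to
#' belong to the same activation event. The rule is applied by transitive
#' chaining: if frames f1, f2 are within the window and f2, f3 are too, all
#' three form one event, regardless of input order. Each event is
#' represented by its first frame. Merging is idempotent.
#'
#' @param frames integer-ish vector of candidate maxima frames.
#' @param merge_window frames; maxima separated by `<= merge_window` chain
#'   into one event (default 3).
#' @return Sorted vector of event frames (one per merged event).
#' @export
merge_peak_frames <- function(frames, merge_window = 3) {
  if (length(frames) == 0L) return(integer(0))
  f <- sort(unique(frames))
  newev <- c(TRUE, diff(f) > merge_window)
  f[newev]
}

#' Detect biosensor activation peaks in an intensity trace
#'
#' Implements the activation-counting rule for ratiometric Cdc42 biosensor
#' traces: the trace is differentiated (first difference at the frame
#' spacing), local maxima of the differential are located, those whose
#' underlying intensity does not exceed the background level are discarded,
#' and surviving maxima within `merge_window` frames of each other are
#' merged into single activation events.
#'
#' "Above background level" is made explicit as intensity greater than
#' mean + `z_cutoff` * SD of the paired background trace (a region of the
#' same movie with no activation).
#'
#' @param trace an `activation_trace` (see [gen_activation_trace()]) or a
#'   numeric intensity vector.
#' @param background background trace (required when `trace` is a bare
#'   vector).
#' @param merge_window event merge window in frames (default 3).
#' @param z_cutoff background z-score a frame must exceed (default 2).
#' @param smooth optional moving-average half-window (frames) applied to the
#'   trace before differentiation; 0 (default) disables smoothing.
#' @return list of class `peak_event_set`: `event_frames`, `count`,
#'   `candidate_frames` (pre-merge), `threshold`, `merge_window`.
#' @export
detect_activation_peaks <- function(trace, background = NULL,
                                    merge_window = 3, z_cutoff = 2,
                                    smooth = 0) {
  if (inherits(trace, "activation_trace")) {
    intensity <- trace$intensity
    if (is.null(background)) background <- trace$background
  } else intensity <- as.numeric(trace)
  if (is.null(background)) stop("a background trace is required")
  n <- length(intensity)
  if (n < 5L) stop("trace too short (need >= 5 frames)", call. = FALSE)
  if (n <= merge_window) stop("trace shorter than merge window", call. = FALSE)
  if (smooth > 0) {
    k <- 2L * as.integer(smooth) + 1L
    intensity <- as.numeric(stats::filter(intensity, rep(1 / k, k),
                                          sides = 2))
  }
  thr <- mean(background) + z_cutoff * sd(background)
  d <- diff(intensity)
  m <- length(d)
  # local maxima of the differential (plateaus resolved to the left edge)
  is_max <- c(FALSE, d[2:(m - 1)] > d[1:(m - 2)] &
                     d[2:(m - 1)] >= d[3:m], FALSE)
  is_max[1] <- d[1] > 0 && d[1] >= d[2]
  is_max[m] <- d[m] > d[m - 1] && d[m] > 0
  cand <- which(is_max & d > 0)
  # underlying intensity at the post-rise frame must clear the background
  cand <- cand[!is.na(intensity[cand + 1L]) & intensity[cand + 1L] > thr]
  ev <- merge_peak_frames(cand + 1L, merge_window)
  structure(list(event_frames = ev, count = length(ev),
                 candidate_frames = cand + 1L, threshold = thr,
                 merge_window = merge_window),
            class = "peak_event_set")
}

#' Activation-peak counts per region
#'
#' Runs [detect_activation_peaks()] on a set of traces grouped by region
#' kind (cell-cell junction vs free leading edge) and summarizes event
#' counts per group, the readout compared between conditions in the
#' biosensor experiments.
#'
#' @param traces list of `activation_trace` objects.
#' @param ... passed to [detect_activation_peaks()].
#' @return list with `per_region` (data.frame: `region_id`, `region_kind`,
#'   `n_events`) and `summary` (per-kind mean, SD, n).
#' @export
peaks_per_region <- function(traces, ...) {
  stopifnot(length(traces) >= 1L)
  per <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    det <- detect_activation_peaks(tr, ...)
    data.frame(region_id = if (!is.null(tr$region_id)) tr$region_id else i,
               region_kind = if (!is.null(tr$region_kind)) tr$region_kind
                             else "junction",
               n_events = det$count)
  }))
  agg <- do.call(rbind, lapply(split(per, per$region_kind), function(g)
    data.frame(region_kind = g$region_kind[1], n = nrow(g),
               mean_events = mean(g$n_events), sd_events = sd(g$n_events))))
  rownames(agg) <- NULL
  list(per_region = per, summary = agg)
}
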