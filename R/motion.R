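#' Gridded velocity field
#'
#' Container for a regular-grid velocity field (e.g. from particle image
#' velocimetry of a migrating monolayer). `u` is the x-component — the
#' component along the direction of wound closure — and the one used for
#' spatial correlation.
#'
#' @param u,v matrices of velocity components (um/h), rows indexing y and
#'   columns x.
#' @param grid_spacing_um node spacing in micrometres.
#' @param valid optional logical matrix flagging trustworthy nodes.
#' @return Object of class `velocity_field`.
#' @export
velocity_field <- function(u, v = NULL, grid_spacing_um = 1, valid = NULL) {
  u <- as.matrix(u)
  if (is.null(v)) v <- matrix(0, nrow(u), ncol(u))
  stopifnot(all(dim(u) == dim(as.matrix(v))))
  .assert_number(grid_spacing_um, "grid_spacing_um", positive = TRUE)
  if (!all(is.finite(u)) || !all(is.finite(as.matrix(v))))
    stop("non-finite velocities", call. = FALSE)
  structure(list(u = u, v = as.matrix(v),
                 grid_spacing_um = grid_spacing_um,
                 valid = valid),
            class = "velocity_field")
}

#' Spatial autocorrelation of the velocity x-component
#'
#' Computes the normalized spatial autocorrelation
#' \eqn{C(r) = \langle u'(x) u'(x+r)\rangle / \langle u'^2\rangle}
#' of the mean-subtracted x-component of a velocity field, with node pairs
#' binned by their separation distance. `C(0) = 1` by construction. The
#' 2-D lag correlation is computed with zero-padded FFTs (so no periodic
#' wrap-around) and then binned radially.
#'
#' @param field a [velocity_field()].
#' @param max_lag_um largest lag retained (default: half the smaller grid
#'   extent).
#' @param bin_width_um lag bin width (default: the grid spacing).
#' @param component `"x"` (default, the wound-closure direction) or
#'   `"isotropic"` (average of x and y components' correlations).
#' @return data.frame of class `correlation_curve` with `lag_um`, `C`,
#'   `n_pairs`.
#' @export
spatial_correlation <- function(field, max_lag_um = NULL, bin_width_um = NULL,
                                component = c("x", "isotropic")) {
  component <- match.arg(component)
  stopifnot(inherits(field, "velocity_field"))
  h <- field$grid_spacing_um
  d <- dim(field$u)
  if (prod(d) < 2L) stop("need >= 2 grid nodes", call. = FALSE)
  if (is.null(max_lag_um)) max_lag_um <- (min(d) - 1) * h / 2
  if (is.null(bin_width_um)) bin_width_um <- h

  comp_curve <- function(u) {
    if (var(as.numeric(u)) < .Machine$double.eps * mean(u^2 + 1))
      stop("zero-variance field: correlation undefined", call. = FALSE)
    up <- u - mean(u)
    P <- 2L * d  # zero-padded size
    pad <- matrix(0, P[1], P[2]); pad[1:d[1], 1:d[2]] <- up
    one <- matrix(0, P[1], P[2]); one[1:d[1], 1:d[2]] <- 1
    F <- fft(pad); G <- fft(one)
    num <- Re(fft(Mod(F)^2, inverse = TRUE)) / prod(P)
    cnt <- Re(fft(Mod(G)^2, inverse = TRUE)) / prod(P)
    list(num = num, cnt = round(cnt))
  }

  cc <- comp_curve(field$u)
  if (component == "isotropic") {
    cc2 <- comp_curve(field$v)
    cc$num <- cc$num + cc2$num
    cc$cnt <- cc$cnt + cc2$cnt
  }
  P <- dim(cc$num)
  # lag vectors for the padded FFT layout
  lx <- c(0:(P[1] / 2 - 1), -(P[1] / 2):-1)
  ly <- c(0:(P[2] / 2 - 1), -(P[2] / 2):-1)
  r <- sqrt(outer(lx^2, ly^2, "+")) * h
  keep <- r <= max_lag_um & cc$cnt > 0
  bin <- floor(r[keep] / bin_width_um + 0.5)  # bin centers at k*bw
  num_b <- tapply(cc$num[keep], bin, sum)
  cnt_b <- tapply(cc$cnt[keep], bin, sum)
  lag <- as.numeric(names(num_b)) * bin_width_um
  Cb <- (num_b / cnt_b)
  Cb <- as.numeric(Cb / Cb[lag == 0])
  out <- data.frame(lag_um = lag, C = Cb, n_pairs = as.numeric(cnt_b))
  out <- out[order(out$lag_um), ]
  rownames(out) <- NULL
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Correlation length from an exponential fit
#'
#' Fits \eqn{C(r) = \exp(-r/\lambda)} to a correlation curve by least
#' squares and returns the decay constant (the correlation length, a
#' measure of how far coordinated motion extends). The amplitude is fixed
#' at 1 because the curve is normalized to `C(0) = 1`; a two-parameter
#' \eqn{A e^{-r/\lambda}} fit is available with `two_param = TRUE`.
#'
#' @param curve a `correlation_curve` (or data.frame with `lag_um`, `C`).
#' @param fit_range optional `c(min, max)` lag range; default uses lags
#'   where `C > 0.05` (and requires at least 4 bins).
#' @param two_param fit amplitude as well (default FALSE).
#' @return Correlation length lambda in micrometres.
#' @export
correlation_length <- function(curve, fit_range = NULL, two_param = FALSE) {
  r <- curve$lag_um; C <- curve$C
  if (is.null(fit_range)) {
    # contiguous run of decaying correlation from the origin
    drop_at <- which(C <= 0.05)
    last <- if (length(drop_at)) min(drop_at) - 1L else length(C)
    keep <- seq_len(max(last, 0L))
  } else {
    keep <- which(r >= fit_range[1] & r <= fit_range[2])
  }
  if (length(keep) < 4L)
    stop("need >= 4 lag bins in the fit range", call. = FALSE)
  r <- r[keep]; C <- C[keep]
  pos <- C > 0 & r > 0
  if (sum(pos) < 2L || stats::coef(stats::lm(log(C[pos]) ~ r[pos]))[2] >= -1e-12)
    stop("correlation curve does not decay: cannot fit", call. = FALSE)
  if (two_param) {
    # log-linear solution (exact on noiseless data), polished by
    # least squares on the original scale
    lf <- stats::lm(log(C[pos]) ~ r[pos])
    start <- c(A = exp(unname(stats::coef(lf)[1])),
               lambda = -1 / unname(stats::coef(lf)[2]))
    sse2 <- function(p) sum((C - p[1] * exp(-r / p[2]))^2)
    fit <- stats::optim(start, sse2, method = "Nelder-Mead",
                        control = list(reltol = 1e-14))
    return(unname(fit$par["lambda"]))
  }
  sse <- function(lambda) sum((C - exp(-r / lambda))^2)
  opt <- optimize(sse, interval = c(min(r[r > 0]) / 100, max(r) * 100),
                  tol = .Machine$double.eps^0.5)
  opt$minimum
}

#' Track-level migration metrics
#'
#' @param track data.frame with time-ordered columns `t_h`, `x_um`, `y_um`
#'   (strictly increasing timestamps, >= 2 points).
#' @return list with `path_length_um` (summed step lengths),
#'   `displacement_um` (start-to-end distance), `straightness`
#'   (displacement / path length, 1 for a straight path), and
#'   `velocity_um_h` (path length / elapsed time).
#' @export
track_metrics <- function(track) {
  stopifnot(all(c("t_h", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2L) stop("track needs >= 2 points", call. = FALSE)
  if (any(diff(track$t_h) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  path <- sum(steps)
  disp <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
               (track$y_um[nrow(track)] - track$y_um[1])^2)
  elapsed <- track$t_h[nrow(track)] - track$t_h[1]
  if (elapsed <= 0) stop("zero elapsed time", call. = FALSE)
  list(path_length_um = path, displacement_um = disp,
       straightness = if (path > 0) disp / path else NA_real_,
       velocity_um_h = path / elapsed)
}

#' Wound closure percentage
#'
#' @param free_area_t0_um2 free (wound) area at time 0; must be > 0.
#' @param free_area_t_um2 free area at the later time.
#' @return list with `closure_percent` (clipped to \[0, 100\]) and `flag`
#'   (`"out_of_range"` if clipping occurred).
#' @export
wound_closure <- function(free_area_t0_um2, free_area_t_um2) {
  .assert_number(free_area_t0_um2, "free_area_t0_um2", positive = TRUE)
  raw <- 100 * (1 - free_area_t_um2 / free_area_t0_um2)
  list(closure_percent = min(max(raw, 0), 100),
       flag = if (raw < 0 || raw > 100) "out_of_range" else "ok")
}

#' Block-matching particle image velocimetry
#'
#' Minimal cross-correlation PIV: the frame pair is tiled into interrogation
#' windows (default 64 px with 50% overlap), the displacement of each window
#' is the peak of the circular cross-correlation, refined to subpixel
#' precision by parabolic interpolation. Windows with no texture or without
#' a dominant peak are flagged invalid.
#'
#' @param frame_a,frame_b same-shape matrices (consecutive frames).
#' @param window interrogation window size in px (default 64).
#' @param overlap window overlap fraction (default 0.5).
#' @param pixel_size_um physical pixel size (default 1).
#' @param dt_h frame interval in hours (default 1).
#' @param peak_snr minimum (peak - mean)/sd of the correlation map for a
#'   node to be valid (default 5).
#' @param subpixel parabolic subpixel refinement (default TRUE).
#' @return A [velocity_field()] with `valid` flags; spacing equals the
#'   window step.
#' @export
block_piv <- function(frame_a, frame_b, window = 64, overlap = 0.5,
                      pixel_size_um = 1, dt_h = 1, peak_snr = 5,
                      subpixel = TRUE) {
  a <- as.matrix(frame_a); b <- as.matrix(frame_b)
  if (!all(dim(a) == dim(b))) stop("frame shapes differ", call. = FALSE)
  if (window > min(dim(a))) stop("window larger than frame", call. = FALSE)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  ys <- seq(1L, nrow(a) - window + 1L, by = step)
  xs <- seq(1L, ncol(a) - window + 1L, by = step)
  u <- v <- matrix(0, length(ys), length(xs))
  valid <- matrix(TRUE, length(ys), length(xs))
  wrap_shift <- function(i) ifelse(i > window / 2, i - window, i)
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    wa <- a[ys[iy]:(ys[iy] + window - 1L), xs[ix]:(xs[ix] + window - 1L)]
    wb <- b[ys[iy]:(ys[iy] + window - 1L), xs[ix]:(xs[ix] + window - 1L)]
    if (sd(wa) == 0 || sd(wb) == 0) { valid[iy, ix] <- FALSE; next }
    cc <- Re(fft(Conj(fft(wa - mean(wa))) * fft(wb - mean(wb)),
                 inverse = TRUE)) / window^2
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    snr <- (max(cc) - mean(cc)) / sd(cc)
    if (!is.finite(snr) || snr < peak_snr) { valid[iy, ix] <- FALSE; next }
    dy <- wrap_shift(pk[1] - 1L); dx <- wrap_shift(pk[2] - 1L)
    if (subpixel) {
      sub1 <- function(cm, c0, cp) {
        den <- cm - 2 * c0 + cp
        if (den >= 0) 0 else (cm - cp) / (2 * den)
      }
      wi <- function(i) ((i - 1L) %% window) + 1L
      dy <- dy + sub1(cc[wi(pk[1] - 1L), pk[2]], cc[pk[1], pk[2]],
                      cc[wi(pk[1] + 1L), pk[2]])
      dx <- dx + sub1(cc[pk[1], wi(pk[2] - 1L)], cc[pk[1], pk[2]],
                      cc[pk[1], wi(pk[2] + 1L)])
    }
    u[iy, ix] <- dx * pixel_size_um / dt_h
    v[iy, ix] <- dy * pixel_size_um / dt_h
  }
  velocity_field(u, v, grid_spacing_um = step * pixel_size_um, valid = valid)
}
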