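# Synthetic-data generators. Every generator records its ground truth so
# each pipeline stage can be tested end to end without external data; they
# reproduce the statistical structure of the assays (von Mises polarity
# angles, spot overlap, step photobleach, peaky activation traces,
# retract adhesion wells, exponentially correlated velocity fields), not
# the underlying biology.

#' Sample from the von Mises circular distribution
#'
#' Best-Fisher rejection sampler. The von Mises distribution is the
#' circular analogue of the Gaussian; its concentration kappa controls how
#' tightly angles cluster around the mean direction, and its mean resultant
#' length (the expected polarity index of a large sample) is the Bessel
#' ratio I1(kappa)/I0(kappa). `kappa = 0` is handled exactly as the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter (>= 0).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(wrap_deg(runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    z <- cos(pi * runif(m))
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    u2 <- runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(runif(sum(acc)) - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
    out <- c(out, th)
  }
  wrap_deg(mu_deg + rad2deg(out[seq_len(n)]))
}

#' Mean resultant length of the von Mises distribution
#'
#' The Bessel-function ratio I1(kappa)/I0(kappa): the polarity index a large
#' von Mises sample converges to.
#'
#' @param kappa concentration (>= 0).
#' @return Expected mean resultant length in \[0, 1).
#' @export
vonmises_mean_resultant <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# ---------------------------------------------------------------- monolayer

#' Kappa-vs-distance profiles for simulated monolayers
#'
#' `kappa_coordinated()` emulates a coordinated monolayer: constant
#' concentration out to `range_um`, zero (uniform angles) beyond — polarity
#' reaches about 300 um into the monolayer from the wound edge.
#' `kappa_floor()` emulates an uncoordinated (junction-disrupted) monolayer:
#' only the geometric polarity bias of the free interface remains — a
#' stronger bias in the leader-row band and a small floor across the
#' edge-proximal region. The default floor (kappa 0.2) has mean resultant
#' length ~0.10, the residual per-bin polarity level reported for
#' alpha-catenin-depleted monolayers.
#'
#' @param kappa,floor_kappa,edge_kappa von Mises concentrations.
#' @param range_um extent of the non-zero region.
#' @param edge_range_um extent of the leader-row band (floor profile).
#' @return A function mapping distance-to-edge (um) to kappa.
#' @export
kappa_coordinated <- function(kappa = 2, range_um = 300) {
  force(kappa); force(range_um)
  function(d) ifelse(d < range_um, kappa, 0)
}

#' @rdname kappa_coordinated
#' @export
kappa_floor <- function(edge_kappa = 0.8, floor_kappa = 0.2,
                        range_um = 300, edge_range_um = 50) {
  force(edge_kappa); force(floor_kappa); force(range_um); force(edge_range_um)
  function(d) ifelse(d < edge_range_um, edge_kappa,
                     ifelse(d < range_um, floor_kappa, 0))
}

#' Specification of a simulated wounded monolayer
#'
#' @param n_cells number of cells (> 0).
#' @param field_size_um `c(edge_length, depth)` in micrometres: extent along
#'   the wound edge and into the monolayer.
#' @param edge_geometry `"straight"` (vertical edge at x = 0, wound at
#'   x < 0) or a list `list(type = "arc", center = c(x, y), radius,
#'   theta_deg = c(from, to))` for a curved sprouting-front geometry (free
#'   space outside the arc).
#' @param kappa_profile function mapping distance-to-edge (um) to the von
#'   Mises concentration of polarity angles (>= 0 everywhere).
#' @param mean_direction_deg mean polarity direction (0 = toward the free
#'   edge).
#' @param golgi_offset_um distance of the Golgi centroid from the nucleus
#'   centroid along the polarity axis (default 5 um).
#' @param nucleus_jitter_um positional jitter of nuclei around their lattice
#'   sites (default: a quarter of the lattice spacing).
#' @param seed RNG seed.
#' @return list of class `monolayer_spec`.
#' @export
monolayer_spec <- function(n_cells = 1000, field_size_um = c(600, 400),
                           edge_geometry = "straight",
                           kappa_profile = kappa_coordinated(),
                           mean_direction_deg = 0, golgi_offset_um = 5,
                           nucleus_jitter_um = NULL, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells <= 0)
    stop("invalid spec: n_cells must be > 0", call. = FALSE)
  if (any(field_size_um <= 0))
    stop("invalid spec: field_size_um must be > 0", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells),
                 field_size_um = field_size_um,
                 edge_geometry = edge_geometry,
                 kappa_profile = kappa_profile,
                 mean_direction_deg = mean_direction_deg,
                 golgi_offset_um = golgi_offset_um,
                 nucleus_jitter_um = nucleus_jitter_um,
                 seed = as.integer(seed)),
            class = "monolayer_spec")
}

#' Simulate a wounded monolayer with known polarity ground truth
#'
#' Places nuclei on a jittered lattice beside the free edge, samples each
#' cell's polarity angle from a von Mises distribution whose concentration
#' depends on the cell's distance to the edge, and puts the Golgi centroid
#' exactly `golgi_offset_um` from the nucleus along the sampled axis. The
#' true sampled angle and distance are recorded per cell.
#'
#' @param spec a [monolayer_spec()].
#' @return list of class `monolayer_sim`: `cells` (data.frame with nucleus /
#'   Golgi centroids, `alpha_true_deg`, `distance_um`, `kappa`), `edge`
#'   (an [edge_reference()]) and `spec`. Deterministic for a fixed seed.
#' @export
gen_monolayer <- function(spec) {
  stopifnot(inherits(spec, "monolayer_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  len <- spec$field_size_um[1]; depth <- spec$field_size_um[2]
  s <- sqrt(len * depth / n)
  jit <- if (is.null(spec$nucleus_jitter_um)) s / 4 else spec$nucleus_jitter_um

  nx <- ceiling(depth / s); ny <- ceiling(len / s)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  if (nrow(g) > n) g <- g[sort(sample.int(nrow(g), n)), ]
  d0 <- (g$ix - 0.5) * depth / nx   # distance into the monolayer
  a0 <- (g$iy - 0.5) * len / ny     # position along the edge
  d0 <- pmin(pmax(d0 + rnorm(nrow(g), 0, jit), 0.1), depth - 0.1)
  a0 <- a0 + rnorm(nrow(g), 0, jit)

  if (identical(spec$edge_geometry, "straight")) {
    edge <- edge_reference(cbind(c(0, 0), c(-0.1 * len, 1.1 * len)),
                           inward_side = "left")
    nuc <- cbind(d0, a0)
  } else if (is.list(spec$edge_geometry) &&
             identical(spec$edge_geometry$type, "arc")) {
    eg <- spec$edge_geometry
    th <- deg2rad(seq(eg$theta_deg[1], eg$theta_deg[2], length.out = 181))
    pl <- cbind(eg$center[1] + eg$radius * cos(th),
                eg$center[2] + eg$radius * sin(th))
    # traveling with increasing theta, the outside of the arc is on the right
    edge <- edge_reference(pl, inward_side = "right")
    thc <- deg2rad(eg$theta_deg[1] +
                     (a0 / len) * diff(eg$theta_deg))
    rr <- eg$radius - d0
    if (any(rr <= 0)) stop("monolayer depth exceeds arc radius")
    nuc <- cbind(eg$center[1] + rr * cos(thc), eg$center[2] + rr * sin(thc))
  } else stop("unknown edge_geometry", call. = FALSE)

  prj <- edge_project(nuc, edge)
  kap <- spec$kappa_profile(prj$distance_um)
  if (any(kap < 0)) stop("kappa_profile returned negative kappa")
  alpha <- numeric(nrow(nuc))
  for (k in unique(kap)) {  # draw per concentration level
    idx <- which(kap == k)
    alpha[idx] <- rvonmises(length(idx), spec$mean_direction_deg, k)
  }
  ar <- deg2rad(alpha)
  # unit polarity axis: cos(alpha) along the inward normal n,
  # sin(alpha) along m = (n_y, -n_x)
  vx <- cos(ar) * prj$normal_x + sin(ar) * prj$normal_y
  vy <- cos(ar) * prj$normal_y - sin(ar) * prj$normal_x
  gol <- nuc + spec$golgi_offset_um * cbind(vx, vy)

  cells <- data.frame(
    cell_id = seq_len(nrow(nuc)),
    nucleus_x_um = nuc[, 1], nucleus_y_um = nuc[, 2],
    golgi_x_um = gol[, 1], golgi_y_um = gol[, 2],
    alpha_true_deg = alpha, distance_um = prj$distance_um, kappa = kap)
  structure(list(cells = cells, edge = edge, spec = spec),
            class = "monolayer_sim")
}

# ---------------------------------------------------------------- coloc

#' Synthetic two-channel spot images with known overlap
#'
#' Generates two spot images whose binary masks overlap by a prescribed
#' fraction of the query (A) mask: a fraction of A's spots are duplicated
#' into B at identical positions, the rest of B's spots are placed away from
#' A. Spots are non-overlapping discs, so the achieved fraction is exact up
#' to spot-count rounding and is recorded as ground truth.
#'
#' @param n_spots_a,n_spots_b spot counts for the two channels.
#' @param overlap_target requested overlap fraction of mask A in \[0, 1\].
#' @param image_shape `c(rows, cols)` in pixels.
#' @param spot_radius_px disc radius (default 3).
#' @param noise_sd intensity noise added to the images (default 0).
#' @param seed RNG seed.
#' @return list: `image_a`, `image_b` (intensity images), `mask_a`,
#'   `mask_b` (0/1), `true_overlap_fraction` (counted on the masks).
#' @export
gen_coloc_pair <- function(n_spots_a, n_spots_b, overlap_target,
                           image_shape = c(128, 128), spot_radius_px = 3,
                           noise_sd = 0, seed = 1L) {
  if (overlap_target < 0 || overlap_target > 1)
    stop("overlap_target must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  r <- spot_radius_px
  min_sep <- 2 * r + 2
  place <- function(k, avoid) {
    centers <- avoid
    out <- matrix(0, 0, 2)
    tries <- 0L
    while (nrow(out) < k) {
      if ((tries <- tries + 1L) > 20000L)
        stop("cannot place spots: image too crowded")
      p <- c(sample(seq(r + 1, image_shape[1] - r), 1),
             sample(seq(r + 1, image_shape[2] - r), 1))
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >=
            min_sep) {
        out <- rbind(out, p); centers <- rbind(centers, p)
      }
    }
    out
  }
  stamp <- function(centers) {
    m <- matrix(0L, image_shape[1], image_shape[2])
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[off$dy^2 + off$dx^2 <= r^2, ]
    for (i in seq_len(nrow(centers))) {
      m[cbind(centers[i, 1] + off$dy, centers[i, 2] + off$dx)] <- 1L
    }
    m
  }
  ca <- place(n_spots_a, matrix(0, 0, 2))
  n_copy <- round(overlap_target * n_spots_a)
  n_copy <- min(n_copy, n_spots_b)
  cb_new <- if (n_spots_b > n_copy)
    place(n_spots_b - n_copy, ca) else matrix(0, 0, 2)
  cb <- rbind(ca[seq_len(n_copy), , drop = FALSE], cb_new)
  ma <- stamp(ca); mb <- stamp(cb)
  truth <- sum(ma & mb) / sum(ma)
  noise <- function() if (noise_sd > 0)
    matrix(rnorm(prod(image_shape), 0, noise_sd), image_shape[1]) else 0
  list(image_a = 200 * ma + 10 + noise(),
       image_b = 200 * mb + 10 + noise(),
       mask_a = ma, mask_b = mb,
       true_overlap_fraction = truth)
}

# ---------------------------------------------------------------- fret

#' Synthetic acceptor-photobleaching donor image pair
#'
#' Constant donor images whose ROI means satisfy
#' `(i_post - i_pre) / i_post = ef_true` exactly before noise.
#'
#' @param ef_true true FRET efficiency, in \[0, 1).
#' @param i_post post-bleach donor intensity (default 100).
#' @param noise_sd pixel noise SD (default 0).
#' @param image_shape `c(rows, cols)`.
#' @param seed RNG seed.
#' @return list: `donor_pre`, `donor_post`, `roi` (central logical mask),
#'   `ef_true`, `i_pre_true`.
#' @export
gen_photobleach_pair <- function(ef_true, i_post = 100, noise_sd = 0,
                                 image_shape = c(64, 64), seed = 1L) {
  if (ef_true < 0 || ef_true >= 1)
    stop("ef_true must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  i_pre <- i_post * (1 - ef_true)
  mk <- function(level) {
    img <- matrix(level, image_shape[1], image_shape[2])
    if (noise_sd > 0)
      img <- img + matrix(rnorm(prod(image_shape), 0, noise_sd),
                          image_shape[1])
    img
  }
  roi <- matrix(FALSE, image_shape[1], image_shape[2])
  q1 <- floor(image_shape / 4)
  roi[(q1[1] + 1):(image_shape[1] - q1[1]),
      (q1[2] + 1):(image_shape[2] - q1[2])] <- TRUE
  list(donor_pre = mk(i_pre), donor_post = mk(i_post), roi = roi,
       ef_true = ef_true, i_pre_true = i_pre)
}

#' Synthetic biosensor activation trace
#'
#' Background-level trace with impulse peaks at the requested frames, paired
#' with a peak-free background trace. The ground-truth event count applies
#' the same 3-frame merge rule the detector uses ([merge_peak_frames()]), so
#' generator and detector share one rule.
#'
#' @param peak_frames 1-based frames of activation maxima (within
#'   `[2, n_frames]`).
#' @param peak_height intensity of each peak above background (default 50).
#' @param background_level baseline intensity (default 100).
#' @param n_frames trace length (default 300; frame interval 1 s).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param region_kind `"junction"` or `"free-edge"`.
#' @param region_id optional identifier.
#' @param merge_window merge window used for the recorded truth (default 3).
#' @param seed RNG seed.
#' @return Object of class `activation_trace`: `time_s`, `intensity`,
#'   `background`, `region_kind`, `region_id`, `truth_event_frames`,
#'   `truth_events`.
#' @export
gen_activation_trace <- function(peak_frames, peak_height = 50,
                                 background_level = 100, n_frames = 300,
                                 noise_sd = 0, region_kind = "junction",
                                 region_id = NULL, merge_window = 3,
                                 seed = 1L) {
  peak_frames <- as.integer(peak_frames)
  if (length(peak_frames) && (min(peak_frames) < 2 ||
                              max(peak_frames) > n_frames))
    stop("peak frames out of bounds", call. = FALSE)
  set.seed(seed)
  intensity <- background_level + rnorm(n_frames, 0, noise_sd)
  intensity[peak_frames] <- intensity[peak_frames] + peak_height
  background <- background_level + rnorm(n_frames, 0, noise_sd)
  ev <- merge_peak_frames(peak_frames, merge_window)
  structure(list(time_s = seq_len(n_frames), intensity = intensity,
                 background = background, region_kind = region_kind,
                 region_id = region_id,
                 truth_event_frames = ev, truth_events = length(ev)),
            class = "activation_trace")
}

# ---------------------------------------------------------------- afm

#' Specification of a synthetic force-distance curve
#'
#' Defaults follow the cell-cell adhesion protocol: 300 pN applied contact
#' force, 5 s contact time.
#'
#' @param contact_force_pN,contact_time_s contact metadata.
#' @param adhesion_depth_pN depth of the triangular retract adhesion well
#'   (> 0 for an adhesive contact; 0 gives a non-adhesive curve).
#' @param adhesion_width_um full width of the well (> 0).
#' @param well_center_um separation at the well minimum (default 2.5).
#' @param baseline_noise_sd_pN force noise (default 0).
#' @param max_separation_um,n_points sampling of the separation axis.
#' @param seed RNG seed.
#' @return list of class `force_curve_spec`.
#' @export
force_curve_spec <- function(contact_force_pN = 300, contact_time_s = 5,
                             adhesion_depth_pN = 100, adhesion_width_um = 2,
                             well_center_um = 2.5, baseline_noise_sd_pN = 0,
                             max_separation_um = 10, n_points = 401,
                             seed = 1L) {
  if (adhesion_depth_pN < 0 || adhesion_width_um <= 0)
    stop("adhesion depth must be >= 0 and width > 0", call. = FALSE)
  structure(as.list(environment()), class = "force_curve_spec")
}

#' Generate a synthetic force-distance curve with known work
#'
#' Approach: soft contact rise near zero separation, flat baseline beyond.
#' Retract: the same contact component plus a triangular adhesion well of
#' the requested depth and width. The analytic enclosed area between the
#' two segments is `0.5 * depth * width` (pN um), recorded as the true
#' detachment work (1 pN um = 1e-3 fJ); the true maximum detachment force is
#' the well depth. The separation grid includes the well vertices so that
#' trapezoid integration of the noiseless curve is exact.
#'
#' @param spec a [force_curve_spec()].
#' @return list: `curve` (a `force_curve`), `true_work_fJ`,
#'   `true_max_force_pN`, `spec`.
#' @export
gen_force_curve <- function(spec) {
  stopifnot(inherits(spec, "force_curve_spec"))
  set.seed(spec$seed)
  w2 <- spec$adhesion_width_um / 2
  verts <- c(spec$well_center_um - w2, spec$well_center_um,
             spec$well_center_um + w2, 0.5)
  s <- sort(unique(c(seq(0, spec$max_separation_um,
                         length.out = spec$n_points), verts)))
  contact <- spec$contact_force_pN * pmax(0, 1 - s / 0.5)
  well <- -spec$adhesion_depth_pN * pmax(0, 1 - abs(s - spec$well_center_um) / w2)
  nz <- function() if (spec$baseline_noise_sd_pN > 0)
    rnorm(length(s), 0, spec$baseline_noise_sd_pN) else 0
  tab <- rbind(
    data.frame(segment = "approach", separation_um = s,
               force_pN = contact + nz()),
    data.frame(segment = "retract", separation_um = s,
               force_pN = contact + well + nz()))
  curve <- parse_curve(tab, contact_force_pN = spec$contact_force_pN,
                       contact_time_s = spec$contact_time_s)
  list(curve = curve,
       true_work_fJ = 0.5 * spec$adhesion_depth_pN *
         spec$adhesion_width_um * 1e-3,
       true_max_force_pN = spec$adhesion_depth_pN,
       spec = spec)
}

# ---------------------------------------------------------------- velocity

#' Specification of a synthetic velocity field
#'
#' @param grid_shape `c(rows, cols)` of grid nodes.
#' @param grid_spacing_um node spacing (um).
#' @param correlation_length_um target decay length of the exponential
#'   spatial autocorrelation (> grid spacing).
#' @param rms_speed_um_h RMS of the fluctuating velocity component; 0 gives
#'   a uniform (constant) field.
#' @param mean_u_um_h mean x-velocity added to the field (default 0).
#' @param seed RNG seed.
#' @return list of class `velocity_field_spec`.
#' @export
velocity_field_spec <- function(grid_shape = c(256, 256),
                                grid_spacing_um = 10,
                                correlation_length_um = 100,
                                rms_speed_um_h = 20, mean_u_um_h = 0,
                                seed = 1L) {
  if (correlation_length_um <= grid_spacing_um)
    stop("correlation_length_um must exceed grid_spacing_um", call. = FALSE)
  structure(as.list(environment()), class = "velocity_field_spec")
}

#' Generate a velocity field with exponential spatial correlation
#'
#' Spectral synthesis: white Gaussian noise is filtered in Fourier space
#' with the spectral density of the 2-D exponential covariance,
#' \eqn{S(k) \propto (1 + (kL)^2)^{-3/2}}, giving a Gaussian random field
#' whose x-component autocorrelation decays as `exp(-r / L)`. u and v are
#' independent realizations.
#'
#' @param spec a [velocity_field_spec()].
#' @return A [velocity_field()].
#' @export
gen_velocity_field <- function(spec) {
  stopifnot(inherits(spec, "velocity_field_spec"))
  set.seed(spec$seed)
  n1 <- spec$grid_shape[1]; n2 <- spec$grid_shape[2]
  h <- spec$grid_spacing_um; L <- spec$correlation_length_um
  if (spec$rms_speed_um_h == 0) {
    u <- matrix(spec$mean_u_um_h, n1, n2)
    return(velocity_field(u, matrix(0, n1, n2), grid_spacing_um = h))
  }
  f1 <- seq_len(n1) - 1L; f1[f1 > n1 / 2] <- f1[f1 > n1 / 2] - n1
  f2 <- seq_len(n2) - 1L; f2[f2 > n2 / 2] <- f2[f2 > n2 / 2] - n2
  kx <- 2 * pi * f1 / (n1 * h); ky <- 2 * pi * f2 / (n2 * h)
  K2 <- outer(kx^2, ky^2, "+")
  amp <- (1 + K2 * L^2)^(-0.75)
  synth <- function() {
    w <- matrix(rnorm(n1 * n2), n1, n2)
    g <- Re(fft(fft(w) * amp, inverse = TRUE)) / (n1 * n2)
    g <- g - mean(g)
    g / sd(g) * spec$rms_speed_um_h
  }
  velocity_field(synth() + spec$mean_u_um_h, synth(), grid_spacing_um = h)
}
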