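# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# von Mises mean resultant length by direct numerical integration
# (independent of besselI and of the sampler)
vm_rho_numint <- function(kappa) {
  num <- integrate(function(t) cos(t) * exp(kappa * cos(t)), -pi, pi,
                   rel.tol = 1e-10)$value
  den <- integrate(function(t) exp(kappa * cos(t)), -pi, pi,
                   rel.tol = 1e-10)$value
  num / den
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# exhaustive minimum-total-distance one-to-one assignment; nuclei rows are
# assigned to a subset/permutation of golgi columns (n_nuc <= n_gol assumed
# after orienting)
brute_force_assignment <- function(nuc, gol) {
  D <- sqrt(outer(nuc[, 1], gol[, 1], "-")^2 +
            outer(nuc[, 2], gol[, 2], "-")^2)
  transposed <- FALSE
  if (nrow(D) > ncol(D)) { D <- t(D); transposed <- TRUE }
  n <- nrow(D); m <- ncol(D)
  perms <- all_perms(m)
  best <- Inf; best_assign <- NULL
  for (i in seq_len(nrow(perms))) {
    sel <- perms[i, seq_len(n)]
    tot <- sum(D[cbind(seq_len(n), sel)])
    if (tot < best) { best <- tot; best_assign <- sel }
  }
  list(total = best, assignment = best_assign, transposed = transposed)
}

# greedy nearest-neighbour assignment total distance (for comparison)
greedy_assignment_total <- function(nuc, gol) {
  D <- sqrt(outer(nuc[, 1], gol[, 1], "-")^2 +
            outer(nuc[, 2], gol[, 2], "-")^2)
  tot <- 0
  for (i in seq_len(min(nrow(D), ncol(D)))) {
    j <- which.min(D[i, ])
    tot <- tot + D[i, j]
    D[, j] <- Inf
  }
  tot
}

# circular box smoothing, used to build textured PIV test frames
.gblur_test <- function(m, k = 2) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m * 0
  for (dy in -k:k) for (dx in -k:k) {
    out <- out + m[((seq_len(n1) - 1 + dy) %% n1) + 1,
                   ((seq_len(n2) - 1 + dx) %% n2) + 1]
  }
  out / (2 * k + 1)^2
}

# simulate one wounded-monolayer image and return records + profile
sim_profile <- function(kappa_profile, seed, n_cells = 600,
                        field = c(600, 400), bin = 50) {
  sim <- gen_monolayer(monolayer_spec(
    n_cells = n_cells, field_size_um = field,
    kappa_profile = kappa_profile, seed = seed))
  rec <- polarity_records(sim$cells[, c("nucleus_x_um", "nucleus_y_um")],
                          sim$cells[, c("golgi_x_um", "golgi_y_um")],
                          sim$edge)
  list(rec = rec, prof = bin_pi_by_distance(rec, bin,
                                            max_distance_um = field[2]),
       sim = sim)
}
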