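test_that("polarity index follows the mean-resultant-vector formula", {
  expect_equal(polarity_index(rep(0, 3))$pi, 1)
  expect_equal(polarity_index(rep(37.5, 100))$pi, 1, tolerance = 1e-12)
  expect_equal(polarity_index(c(0, 90, 180, 270))$pi, 0, tolerance = 1e-12)
  r <- polarity_index(c(0, 90))
  expect_equal(r$pi, sqrt(2) / 2)
  expect_equal(r$mean_angle_deg, 45)
  expect_equal(r$n, 2L)
  expect_error(polarity_index(numeric(0)))
  expect_error(polarity_index(c(0, NA)))
})

test_that("polarity index is rotation, order and duplication invariant", {
  set.seed(42)
  for (i in 1:5) {
    a <- runif(50, -180, 180)
    base <- polarity_index(a)
    shift <- runif(1, -360, 360)
    rot <- polarity_index(a + shift)
    expect_equal(rot$pi, base$pi, tolerance = 1e-12)
    expect_lt(ang_diff(rot$mean_angle_deg, base$mean_angle_deg + shift), 1e-8)
    expect_equal(polarity_index(sample(a))$pi, base$pi, tolerance = 1e-12)
    expect_equal(polarity_index(c(a, a))$pi, base$pi, tolerance = 1e-12)
  }
})

test_that("polarity angle is measured against the inward edge normal", {
  # vertical edge at x = 0, wound at x < 0
  e <- edge_reference(cbind(c(0, 0), c(0, 100)), inward_side = "left")
  expect_equal(polarity_angle(c(10, 0), c(5, 0), e), 0)       # toward wound
  expect_equal(polarity_angle(c(10, 0), c(10, 5), e), 90)     # perpendicular
  expect_equal(polarity_angle(c(10, 0), c(15, 0), e), 180)    # anti-aligned
  expect_warning(a <- polarity_angle(c(10, 0), c(10, 0), e),
                 "zero-length")
  expect_true(is.na(a))
  # flipping the declared free side flips the angle by 180
  e2 <- edge_reference(cbind(c(0, 0), c(0, 100)), inward_side = "right")
  expect_equal(abs(polarity_angle(c(10, 0), c(5, 0), e2)), 180)
})

test_that("distance to a polyline edge is the nearest-segment distance", {
  e <- edge_reference(rbind(c(0, 0), c(100, 0), c(100, 100)), "left")
  expect_equal(distance_to_edge(rbind(c(50, 30)), e), 30)
  expect_equal(distance_to_edge(rbind(c(130, 50)), e), 30)
  # beyond the last vertex: distance to the endpoint
  expect_equal(distance_to_edge(rbind(c(103, 104)), e), 5)
})

test_that("distance binning uses half-open 50 um bins from the edge", {
  rec <- data.frame(alpha_deg = c(0, 0, 0), distance_um = c(10, 60, 110))
  p <- bin_pi_by_distance(rec)
  expect_equal(p$n, c(1L, 1L, 1L))
  expect_equal(p$pi, c(1, 1, 1))
  expect_equal(p$bin_start_um, c(0, 50, 100))
  # a cell exactly on a boundary belongs to the farther bin
  p2 <- bin_pi_by_distance(data.frame(alpha_deg = 0, distance_um = 50),
                           max_distance_um = 100)
  expect_equal(p2$n, c(0L, 1L))
  expect_true(is.na(p2$pi[1]))
})

test_that("binned PI decreases when concentration decays with distance", {
  # large-n per-bin PIs track the Bessel-ratio expectation per bin
  prof <- function(d) ifelse(d < 100, 4, ifelse(d < 200, 2,
                      ifelse(d < 300, 1, 0.5)))
  out <- sim_profile(prof, seed = 99, n_cells = 40000, bin = 100)
  expected <- sapply(c(4, 2, 1, 0.5), vm_rho_numint)
  expect_equal(out$prof$pi, expected, tolerance = 0.02)
  expect_true(all(diff(out$prof$pi) < 0))
})

test_that("threshold rule is mean + SD of pooled per-bin PIs", {
  expect_equal(derive_threshold(c(0.06, 0.14, 0.10)), 0.14)
  expect_equal(derive_threshold(rep(0.2, 5)), 0.2)
  expect_error(derive_threshold(0.1), "2 contributing bins")
  # translation covariance
  v <- c(0.06, 0.14, 0.10, 0.09)
  expect_equal(derive_threshold(v + 0.05), derive_threshold(v) + 0.05)
  # first-bin exclusion on profiles
  prof <- structure(data.frame(bin_start_um = c(0, 50, 100, 150),
                               bin_end_um = c(50, 100, 150, 200),
                               n = c(10L, 10L, 10L, 10L),
                               pi = c(0.9, 0.06, 0.14, 0.10),
                               mean_angle_deg = 0),
                    class = c("polarity_profile", "data.frame"))
  expect_equal(derive_threshold(prof), 0.14)
  expect_gt(derive_threshold(prof, exclude_first_bin = FALSE), 0.14)
})

test_that("angular histogram covers the circle with wrapped half-open bins", {
  h <- angular_histogram(rep(0, 10), n_bins = 24)
  expect_equal(sum(h$count), 10)
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(h$count[h$bin_start_deg == 0], 10)
  # -179 and 179 land in the two circularly adjacent end bins
  h2 <- angular_histogram(c(-179, 179), n_bins = 24)
  expect_equal(h2$count[1], 1L)
  expect_equal(h2$count[24], 1L)
  set.seed(3)
  h3 <- angular_histogram(runif(24000, -180, 180), n_bins = 24)
  expect_equal(sum(h3$count), 24000)
  expect_true(all(abs(h3$count - 1000) < 5 * sqrt(1000)))
})

test_that("Rayleigh test separates aligned from uniform samples", {
  set.seed(11)
  expect_lt(rayleigh_test(rnorm(100, 0, 5))$p_value, 1e-6)
  z0 <- rayleigh_test(c(0, 90, 180, 270, 0, 90, 180, 270))
  expect_equal(z0$statistic, 0, tolerance = 1e-20)
  expect_gt(z0$p_value, 0.99)
  expect_error(rayleigh_test(c(0, 10, 20, 30)), "n >= 5")
  # calibration under the null: rejection rate near nominal
  set.seed(12)
  p <- replicate(400, rayleigh_test(runif(100, 0, 360))$p_value)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.10)
})
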