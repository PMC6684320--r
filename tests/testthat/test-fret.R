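test_that("FRET efficiency follows (Ipost - Ipre)/Ipost", {
  img <- function(v) matrix(v, 16, 16)
  roi <- matrix(TRUE, 16, 16)
  expect_equal(fret_efficiency(img(80), img(80), roi)$ef, 0)
  expect_equal(fret_efficiency(img(60), img(100), roi)$ef, 0.4)
  # Ipre -> 0 gives the upper limit 1
  expect_equal(fret_efficiency(img(0), img(100), roi)$ef, 1)
  expect_error(fret_efficiency(img(50), img(0), roi), "post-bleach")
  r <- fret_efficiency(img(120), img(100), roi)
  expect_lt(r$ef, 0)
  expect_equal(r$flag, "donor_loss")
})

test_that("EF is invariant to intensity scaling and robust to pixel noise", {
  p <- gen_photobleach_pair(0.3, i_post = 100, noise_sd = 2,
                            image_shape = c(80, 80), seed = 4)
  e1 <- fret_efficiency(p$donor_pre, p$donor_post, p$roi)$ef
  e2 <- fret_efficiency(3 * p$donor_pre, 3 * p$donor_post, p$roi)$ef
  expect_equal(e1, e2, tolerance = 1e-12)
  # Monte-Carlo recovery of a known efficiency
  p2 <- gen_photobleach_pair(0.2, i_post = 100, noise_sd = 1,
                             image_shape = c(100, 100), seed = 8)
  expect_equal(fret_efficiency(p2$donor_pre, p2$donor_post, p2$roi)$ef, 0.2,
               tolerance = 0.01)
})

test_that("ratio map excludes zero-donor pixels instead of dividing", {
  d <- matrix(2, 8, 8); f <- 2 * d
  m <- matrix(TRUE, 8, 8)
  r <- ratio_map(d, f, m)
  expect_true(all(r == 2))
  d[3, 3] <- 0
  r2 <- ratio_map(d, f, m)
  expect_true(is.na(r2[3, 3]))
  expect_false(any(is.infinite(r2), na.rm = TRUE))
  # synthetic gradient
  d3 <- matrix(seq(1, 4, length.out = 64), 8)
  f3 <- matrix(seq(2, 12, length.out = 64), 8)
  expect_equal(ratio_map(d3, f3, m), f3 / d3, tolerance = 1e-12)
  expect_error(ratio_map(d, f, matrix(FALSE, 8, 8)), "empty")
})

test_that("peak-frame merging chains within the 3-frame window and is idempotent", {
  expect_equal(merge_peak_frames(c(10, 12)), 10)
  expect_equal(merge_peak_frames(c(10, 20)), c(10, 20))
  expect_equal(merge_peak_frames(c(5, 7, 9, 30)), c(5, 30))
  expect_equal(merge_peak_frames(c(30, 9, 5, 7)), c(5, 30))  # order-free
  m <- merge_peak_frames(c(1, 3, 6, 11, 13, 30))
  expect_equal(merge_peak_frames(m), m)                       # idempotent
  expect_true(all(diff(m) > 3))
  expect_equal(merge_peak_frames(integer(0)), integer(0))
})

test_that("activation peaks are detected exactly at zero noise", {
  tr <- gen_activation_trace(c(10, 12, 40, 80), n_frames = 100,
                             noise_sd = 0)
  d <- detect_activation_peaks(tr)
  expect_equal(d$count, tr$truth_events)     # 3: {10,12} merge
  expect_equal(d$event_frames, c(10, 40, 80))
  # flat trace at background: no events
  flat <- gen_activation_trace(integer(0), n_frames = 50, noise_sd = 0)
  expect_equal(detect_activation_peaks(flat)$count, 0L)
  expect_error(detect_activation_peaks(numeric(3), background = numeric(3)),
               "short")
})

test_that("peak count is invariant to adding a constant to trace and background", {
  tr <- gen_activation_trace(c(15, 40, 70), n_frames = 90, noise_sd = 3,
                             seed = 6)
  d1 <- detect_activation_peaks(tr)
  tr2 <- tr
  tr2$intensity <- tr$intensity + 500
  tr2$background <- tr$background + 500
  d2 <- detect_activation_peaks(tr2)
  expect_equal(d1$event_frames, d2$event_frames)
})

test_that("noisy counts stay within one event of truth at 5x SNR", {
  # peak height 50, noise SD 10; z = 3 keeps chance exceedances from
  # inflating counts (see the methods vignette on the z-cutoff)
  errs <- vapply(1:100, function(s) {
    tr <- gen_activation_trace(c(20, 50, 80), peak_height = 50,
                               noise_sd = 10, n_frames = 100, seed = s)
    detect_activation_peaks(tr, z_cutoff = 3)$count - tr$truth_events
  }, numeric(1))
  expect_lte(mean(abs(errs)), 1)
  expect_gte(mean(abs(errs) <= 1), 0.9)
})

test_that("per-region summaries aggregate counts by region kind", {
  traces <- list(
    gen_activation_trace(c(10, 30), n_frames = 60, region_kind = "junction",
                         region_id = "j1"),
    gen_activation_trace(c(10, 20, 40), n_frames = 60,
                         region_kind = "junction", region_id = "j2"),
    gen_activation_trace(integer(0), n_frames = 60,
                         region_kind = "free-edge", region_id = "e1"))
  pr <- peaks_per_region(traces)
  expect_equal(pr$per_region$n_events, c(2L, 3L, 0L))
  s <- pr$summary
  expect_equal(s$mean_events[s$region_kind == "junction"], 2.5)
  expect_equal(s$mean_events[s$region_kind == "free-edge"], 0)
})
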