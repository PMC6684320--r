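test_that("curve parsing splits, sorts and round-trips segments", {
  g <- gen_force_curve(force_curve_spec(seed = 2))
  s <- g$curve$approach
  tab <- rbind(data.frame(segment = "approach", separation_um = s$separation_um,
                          force_pN = s$force_pN),
               data.frame(segment = "retract",
                          separation_um = g$curve$retract$separation_um,
                          force_pN = g$curve$retract$force_pN))
  # shuffle rows: identical curve after parsing
  tab2 <- tab[sample(nrow(tab)), ]
  p <- parse_curve(tab2)
  expect_equal(p$approach, g$curve$approach)
  expect_equal(p$retract, g$curve$retract)
  expect_error(parse_curve(tab[tab$segment == "approach", ]),
               "missing segment")
  dup <- rbind(tab, data.frame(segment = "retract", separation_um = 0,
                               force_pN = 0))
  expect_warning(parse_curve(dup), "non-monotone")
})

test_that("detachment work equals the analytic enclosed area", {
  g <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 100,
                                        adhesion_width_um = 2))
  w <- detachment_work(g$curve)
  expect_equal(w$work_fJ, 0.1, tolerance = 1e-9)
  expect_equal(w$flag, "ok")
  # retract = approach: zero work
  flat <- g$curve
  flat$retract <- flat$approach
  w0 <- detachment_work(flat)
  expect_equal(w0$work_fJ, 0)
  expect_equal(w0$flag, "no_adhesion_well")
  # two stacked wells: work is additive
  s <- seq(0, 10, by = 0.005)
  tri <- function(c0, d, w) -d * pmax(0, 1 - abs(s - c0) / (w / 2))
  tab <- rbind(
    data.frame(segment = "approach", separation_um = s, force_pN = 0),
    data.frame(segment = "retract", separation_um = s,
               force_pN = tri(2, 100, 1) + tri(5, 50, 2)))
  w2 <- detachment_work(parse_curve(tab))
  expect_equal(w2$work_fJ, (0.5 * 100 * 1 + 0.5 * 50 * 2) * 1e-3,
               tolerance = 1e-6)
  # retract-only mode agrees when the approach is flat
  expect_equal(detachment_work(parse_curve(tab), mode = "retract")$work_fJ,
               w2$work_fJ, tolerance = 1e-9)
})

test_that("work is invariant to a common force offset (baseline correction)", {
  g <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 120,
                                        adhesion_width_um = 1.5))
  w1 <- detachment_work(g$curve)$work_fJ
  sh <- g$curve
  sh$approach$force_pN <- sh$approach$force_pN + 37
  sh$retract$force_pN <- sh$retract$force_pN + 37
  expect_equal(detachment_work(sh)$work_fJ, w1, tolerance = 1e-9)
  expect_equal(max_detachment_force(sh), 120, tolerance = 1e-9)
})

test_that("halving the sampling density changes trapezoid work by < 1%", {
  g <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 100,
                                        adhesion_width_um = 2,
                                        n_points = 801))
  half <- g$curve
  keep <- seq(1, nrow(half$approach), by = 2)
  half$approach <- half$approach[keep, ]
  half$retract <- half$retract[keep, ]
  w_full <- detachment_work(g$curve)$work_fJ
  w_half <- detachment_work(half)$work_fJ
  expect_lt(abs(w_half - w_full) / w_full, 0.01)
})

test_that("maximum detachment force reads the deepest retract excursion", {
  g <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 200))
  expect_equal(max_detachment_force(g$curve), 200, tolerance = 1e-9)
  g0 <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 0))
  expect_equal(max_detachment_force(g0$curve), 0)
  # noisy recovery within the Monte-Carlo bound
  set.seed(44)
  fs <- vapply(1:20, function(s) {
    gn <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 100,
                                           baseline_noise_sd_pN = 5,
                                           seed = s))
    max_detachment_force(gn$curve)
  }, numeric(1))
  expect_true(all(abs(fs - 100) < 15))
})

test_that("cadherin-dependent fraction uses a strict 150 pN threshold", {
  expect_equal(cadherin_fraction(c(100, 200, 160, 140)), 50)
  expect_equal(cadherin_fraction(c(10, 20)), 0)
  expect_equal(cadherin_fraction(c(200, 300)), 100)
  expect_equal(cadherin_fraction(c(150, 151)), 50)  # strictly above
  expect_error(cadherin_fraction(numeric(0)), "empty")
  # monotone non-increasing in the threshold
  set.seed(9)
  f <- runif(200, 0, 400)
  fr <- vapply(seq(0, 400, 50), function(th) cadherin_fraction(f, th),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("force histogram bins counts at 25 pN by default", {
  h <- force_histogram(c(10, 30, 30, 260))
  expect_equal(sum(h$count), 4L)
  expect_equal(h$count[1], 1L)
  expect_equal(h$count[2], 2L)
  expect_equal(h$bin_start_pN[which(h$count == 1L)[2]], 250)
})
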