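test_that("spatial correlation is normalized and mean-invariant", {
  set.seed(5)
  f <- gen_velocity_field(velocity_field_spec(grid_shape = c(64, 64),
                                              seed = 5))
  cc <- spatial_correlation(f, max_lag_um = 200)
  expect_equal(cc$C[cc$lag_um == 0], 1)
  expect_true(all(diff(cc$lag_um) > 0))
  # adding a constant to u leaves C unchanged (mean subtraction)
  f2 <- velocity_field(f$u + 42, f$v, grid_spacing_um = f$grid_spacing_um)
  cc2 <- spatial_correlation(f2, max_lag_um = 200)
  expect_equal(cc2$C, cc$C, tolerance = 1e-9)
  # constant field: zero variance is an error
  fc <- velocity_field(matrix(3, 16, 16), grid_spacing_um = 10)
  expect_error(spatial_correlation(fc), "zero-variance")
})

test_that("correlation length fits noiseless exponentials exactly", {
  r <- seq(0, 500, by = 10)
  lam <- correlation_length(data.frame(lag_um = r, C = exp(-r / 100)))
  expect_equal(lam, 100, tolerance = 1e-6)
  # doubling all lags doubles lambda
  lam2 <- correlation_length(data.frame(lag_um = 2 * r, C = exp(-r / 100)))
  expect_equal(lam2, 200, tolerance = 1e-5)
  # non-decaying curve is an error
  expect_error(correlation_length(data.frame(lag_um = r,
                                             C = rep(0.9, length(r)))),
               "decay")
  expect_error(correlation_length(data.frame(lag_um = r[1:3],
                                             C = exp(-r[1:3] / 100))),
               "4 lag bins")
  # two-parameter mode recovers amplitude-scaled curves
  lam3 <- correlation_length(data.frame(lag_um = r, C = 0.8 * exp(-r / 120)),
                             fit_range = c(0, 500), two_param = TRUE)
  expect_equal(lam3, 120, tolerance = 1e-4)
})

test_that("correlation length of a synthesized 100 um field is recovered", {
  f <- gen_velocity_field(velocity_field_spec(seed = 1))
  cc <- spatial_correlation(f, max_lag_um = 400)
  lam <- correlation_length(cc)
  expect_lt(abs(lam - 100) / 100, 0.1)
})

test_that("track metrics decompose into path, displacement and straightness", {
  straight <- data.frame(t_h = 0:4, x_um = seq(0, 100, 25), y_um = 0)
  m <- track_metrics(straight)
  expect_equal(m$straightness, 1)
  expect_equal(m$path_length_um, 100)
  expect_equal(m$velocity_um_h, 25)
  # out-and-back: zero displacement
  back <- data.frame(t_h = 0:2, x_um = c(0, 50, 0), y_um = 0)
  expect_equal(track_metrics(back)$straightness, 0)
  # L-shaped path
  lpath <- data.frame(t_h = 0:2, x_um = c(0, 50, 50), y_um = c(0, 0, 50))
  ml <- track_metrics(lpath)
  expect_equal(ml$displacement_um, sqrt(5000))
  expect_equal(ml$straightness, sqrt(5000) / 100, tolerance = 1e-12)
  expect_error(track_metrics(straight[1, ]), "2 points")
  expect_error(track_metrics(data.frame(t_h = c(0, 0), x_um = 0:1,
                                        y_um = 0)), "increasing")
})

test_that("straightness never exceeds one", {
  set.seed(13)
  for (i in 1:20) {
    tr <- data.frame(t_h = 0:10, x_um = cumsum(rnorm(11)),
                     y_um = cumsum(rnorm(11)))
    expect_lte(track_metrics(tr)$straightness, 1)
  }
})

test_that("wound closure is the fractional free-area loss", {
  expect_equal(wound_closure(1000, 250)$closure_percent, 75)
  expect_equal(wound_closure(1000, 1000)$closure_percent, 0)
  expect_equal(wound_closure(1000, 0)$closure_percent, 100)
  over <- wound_closure(1000, 1200)
  expect_equal(over$closure_percent, 0)
  expect_equal(over$flag, "out_of_range")
  expect_error(wound_closure(0, 10), "free_area_t0")
})

test_that("block PIV recovers known shifts and flags featureless windows", {
  set.seed(23)
  base <- matrix(rnorm(128 * 128), 128)
  base <- .gblur_test(base)
  shifted <- base[, c(126:128, 1:125)]   # circular shift +3 px in x
  f <- block_piv(base, shifted, window = 64, overlap = 0.5,
                 pixel_size_um = 1, dt_h = 1)
  expect_true(all(f$valid))
  expect_equal(as.numeric(f$u), rep(3, length(f$u)), tolerance = 0.05)
  expect_equal(as.numeric(f$v), rep(0, length(f$v)), tolerance = 0.05)
  # identical frames: zero field
  f0 <- block_piv(base, base, window = 64)
  expect_true(all(abs(f0$u) < 1e-9))
  # independent noise pair: majority of nodes invalid
  fn <- block_piv(matrix(rnorm(128 * 128), 128),
                  matrix(rnorm(128 * 128), 128), window = 64)
  expect_gt(mean(!fn$valid), 0.5)
  # featureless window
  fz <- block_piv(matrix(0, 64, 64), matrix(0, 64, 64), window = 64)
  expect_false(any(fz$valid))
})
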