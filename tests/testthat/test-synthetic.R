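test_that("generators are bit-identical for a fixed seed", {
  s <- monolayer_spec(n_cells = 100, seed = 7)
  expect_identical(gen_monolayer(s)$cells, gen_monolayer(s)$cells)
  f <- velocity_field_spec(grid_shape = c(32, 32), seed = 7)
  expect_identical(gen_velocity_field(f)$u, gen_velocity_field(f)$u)
  expect_identical(gen_coloc_pair(10, 10, 0.5, seed = 7)$mask_a,
                   gen_coloc_pair(10, 10, 0.5, seed = 7)$mask_a)
})

test_that("monolayer spec is validated", {
  expect_error(monolayer_spec(n_cells = 0), "n_cells")
  expect_error(monolayer_spec(field_size_um = c(-1, 100)), "field_size")
  expect_error(rvonmises(10, 0, -1), "kappa")
})

test_that("every Golgi lies exactly golgi_offset from its nucleus along the sampled axis", {
  sim <- gen_monolayer(monolayer_spec(n_cells = 300, golgi_offset_um = 7,
                                      seed = 5))
  v <- cbind(sim$cells$golgi_x_um - sim$cells$nucleus_x_um,
             sim$cells$golgi_y_um - sim$cells$nucleus_y_um)
  expect_equal(sqrt(rowSums(v^2)), rep(7, 300), tolerance = 1e-12)
  # the recovered polarity angle equals the sampled truth
  rec <- polarity_records(sim$cells[, 2:3], sim$cells[, 4:5], sim$edge)
  expect_lt(max(ang_diff(rec$alpha_deg, sim$cells$alpha_true_deg)), 1e-8)
  expect_equal(rec$distance_um, sim$cells$distance_um, tolerance = 1e-12)
})

test_that("von Mises sampler matches the numerical-integration oracle", {
  set.seed(31)
  for (k in c(0.5, 2)) {
    r <- polarity_index(rvonmises(5e4, 30, k))
    expect_equal(r$pi, vm_rho_numint(k), tolerance = 0.01)
    expect_lt(ang_diff(r$mean_angle_deg, 30), 2)
  }
  # kappa = 0 is exactly uniform
  set.seed(32)
  expect_lt(polarity_index(rvonmises(5e4, 0, 0))$pi, 0.02)
})

test_that("arc-front geometry yields the same polarity structure", {
  geom <- list(type = "arc", center = c(0, 0), radius = 500,
               theta_deg = c(0, 90))
  sim <- gen_monolayer(monolayer_spec(
    n_cells = 2000, field_size_um = c(700, 200), edge_geometry = geom,
    kappa_profile = kappa_coordinated(kappa = 4, range_um = 1e4), seed = 9))
  expect_true(all(sim$cells$distance_um >= 0))
  rec <- polarity_records(sim$cells[, 2:3], sim$cells[, 4:5], sim$edge)
  expect_lt(max(ang_diff(rec$alpha_deg, sim$cells$alpha_true_deg)), 1e-6)
  expect_gt(polarity_index(rec$alpha_deg)$pi, 0.8)
})

test_that("coloc pair generator hits the requested overlap", {
  g1 <- gen_coloc_pair(20, 20, 1, seed = 3)
  expect_equal(g1$true_overlap_fraction, 1)
  expect_identical(g1$mask_a, g1$mask_b)
  g0 <- gen_coloc_pair(20, 20, 0, seed = 3)
  expect_equal(g0$true_overlap_fraction, 0)
  g4 <- gen_coloc_pair(50, 50, 0.4, seed = 3)
  expect_lt(abs(g4$true_overlap_fraction - 0.4), 0.02)
  expect_error(gen_coloc_pair(10, 10, 1.2), "overlap_target")
})

test_that("photobleach pair satisfies the EF identity before noise", {
  p0 <- gen_photobleach_pair(0, noise_sd = 0)
  expect_equal(mean(p0$donor_pre[p0$roi]), mean(p0$donor_post[p0$roi]))
  p4 <- gen_photobleach_pair(0.4, i_post = 100, noise_sd = 0)
  expect_equal(p4$i_pre_true, 60)
  expect_equal(mean(p4$donor_pre[p4$roi]), 60)
  expect_error(gen_photobleach_pair(1), "ef_true")
  expect_error(gen_photobleach_pair(-0.1), "ef_true")
})

test_that("activation-trace truth applies the 3-frame merge rule", {
  expect_equal(gen_activation_trace(c(10, 12), n_frames = 50)$truth_events, 1L)
  expect_equal(gen_activation_trace(c(10, 20, 30),
                                    n_frames = 50)$truth_events, 3L)
  # transitive chaining: 5,7,9 chain into one event
  expect_equal(gen_activation_trace(c(5, 7, 9, 30),
                                    n_frames = 50)$truth_events, 2L)
  expect_error(gen_activation_trace(c(10, 60), n_frames = 50), "bounds")
})

test_that("force-curve generator records the analytic work and max force", {
  g <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 100,
                                        adhesion_width_um = 2))
  expect_equal(g$true_work_fJ, 0.1)  # 0.5 * 100 pN * 2 um = 1e-16 J
  expect_equal(g$true_max_force_pN, 100)
  g0 <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 0))
  expect_equal(g0$true_work_fJ, 0)
  expect_equal(g0$true_max_force_pN, 0)
  g2 <- gen_force_curve(force_curve_spec(adhesion_depth_pN = 200))
  expect_equal(g2$true_max_force_pN, 200)
  # zero-noise curve integrates to the analytic area to 1e-6 relative
  w <- detachment_work(g$curve)
  expect_equal(w$work_fJ, g$true_work_fJ, tolerance = 1e-6)
})

test_that("velocity-field generator produces the requested correlation structure", {
  # uniform field at zero rms
  f0 <- gen_velocity_field(velocity_field_spec(grid_shape = c(16, 16),
                                               rms_speed_um_h = 0,
                                               mean_u_um_h = 5))
  expect_true(all(f0$u == 5))
  # node-independent noise decorrelates beyond lag 0
  set.seed(17)
  fn <- velocity_field(matrix(rnorm(64 * 64), 64), grid_spacing_um = 10)
  cc <- spatial_correlation(fn, max_lag_um = 200)
  expect_equal(cc$C[cc$lag_um == 0], 1)
  expect_lt(max(abs(cc$C[cc$lag_um > 0])), 0.1)
  # synthesized exponential correlation tracks exp(-r/L)
  f <- gen_velocity_field(velocity_field_spec(seed = 1))
  cv <- spatial_correlation(f, max_lag_um = 400)
  sub <- cv[cv$lag_um <= 300, ]
  expect_lt(max(abs(sub$C - exp(-sub$lag_um / 100))), 0.05)
  expect_error(velocity_field_spec(grid_spacing_um = 10,
                                   correlation_length_um = 5), "exceed")
})
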