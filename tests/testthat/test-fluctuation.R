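test_that("pooled deviations remove per-trajectory means", {
  traj <- data.frame(cell_id = rep(1:2, each = 6),
                     x_um = c(rep(1.2, 6), rep(1.8, 6) + 0.01 * (0:5)),
                     y_um = 0)
  dev <- pool_deviations(traj)
  expect_equal(dev$dx_um[dev$cell_id == 1], rep(0, 6))
  expect_equal(mean(dev$dx_um[dev$cell_id == 2]), 0)
  # two shifted copies of the same shape pool to identical deviations
  shape <- sin(1:8)
  tr2 <- data.frame(cell_id = rep(1:2, each = 8),
                    x_um = c(shape + 5, shape - 3), y_um = 0)
  d2 <- pool_deviations(tr2)
  expect_equal(d2$dx_um[d2$cell_id == 1], d2$dx_um[d2$cell_id == 2])
  # short trajectories are excluded
  tr3 <- rbind(traj, data.frame(cell_id = 3, x_um = 1:3, y_um = 0))
  expect_message(d3 <- pool_deviations(tr3), "excluded")
  expect_equal(attr(d3, "n_excluded"), 1)
})

test_that("asymmetric Gaussian fit recovers generating sigmas within 3%", {
  set.seed(21)
  n <- 5e4
  dev <- data.frame(dx_um = rnorm(n, 0, 0.06), dy_um = rnorm(n, 0, 0.04))
  fit <- fit_asymmetric_gaussian(dev)
  expect_equal(fit$sigma_long, 0.06, tolerance = 0.03)
  expect_equal(fit$sigma_short, 0.04, tolerance = 0.03)
  # binned least-squares route agrees with maximum likelihood
  fitb <- fit_asymmetric_gaussian(dev, method = "binned")
  expect_equal(fitb$sigma_long, fit$sigma_long, tolerance = 0.05)
  # isotropic input: both axes agree within error
  dev_iso <- data.frame(dx_um = rnorm(n, 0, 0.05),
                        dy_um = rnorm(n, 0, 0.05))
  fi <- fit_asymmetric_gaussian(dev_iso)
  expect_lt(abs(fi$sigma_long - fi$sigma_short),
            4 * (fi$sigma_long_se + fi$sigma_short_se))
  # ML sigma of a zero-mean Gaussian equals the RMS deviation
  expect_equal(fit$sigma_long, sqrt(mean(dev$dx_um^2)))
  expect_error(fit_asymmetric_gaussian(dev[1:50, ]), "at least")
})

test_that("sigma recovery works end-to-end at the locus-tracking design", {
  # scaled-down sampling design: fewer cells than the experiment but same
  # frame interval and duration; tolerance per the recovery requirement
  g <- gen_locus_fluctuation(n_cells = 120, seed = 5)
  dev <- pool_deviations(g$data)
  fit <- fit_asymmetric_gaussian(dev)
  expect_equal(fit$sigma_long, g$truth$sigma_long, tolerance = 0.05)
  expect_equal(fit$sigma_short, g$truth$sigma_short, tolerance = 0.05)
})

test_that("spring-constant conversion reproduces the measured constants", {
  # sigma = 0.064 um -> 0.001 pN/nm; sigma = 0.038 um -> 0.003 pN/nm (1 s.f.)
  expect_equal(report_signif(sigma_to_kspring(0.064)$k_pN_per_nm, 1), 0.001)
  expect_equal(report_signif(sigma_to_kspring(0.038)$k_pN_per_nm, 1), 0.003)
  # sigma = 0.06 um -> k/kT = 278 um^-2, 280 at 2 s.f.
  expect_equal(report_signif(sigma_to_kspring(0.06)$k_over_kT_um2, 2), 280)
  # round trip: sigma -> k/kT -> sigma is exact
  k <- sigma_to_kspring(0.0573)
  expect_equal(1 / sqrt(k$k_over_kT_um2), 0.0573)
})

test_that("drag and elastic force estimates agree within a factor ~2", {
  fd <- drag_force(v = 0.003, D = 1e-4)
  expect_equal(report_signif(fd$force_pN, 1), 0.1)
  fe <- elastic_force(k_sp = 0.001, sigma = 60)
  expect_equal(fe$force_pN, 0.06)
  ratio <- fd$force_pN / fe$force_pN
  expect_gt(ratio, 1)
  expect_lt(ratio, 3)
  # linearity and zeros
  expect_equal(drag_force(0, 1e-4)$force_pN, 0)
  expect_equal(drag_force(0.006, 1e-4)$force_pN, 2 * fd$force_pN)
  expect_equal(elastic_force(0, 60)$force_pN, 0)
})

test_that("optimal hydrolysis time is sigma^2/D with quadratic scaling", {
  opt <- optimal_hydrolysis_time(0.06, 1e-4)
  expect_equal(opt$attachment_time_s, 36)
  expect_equal(report_signif(opt$rate_per_s, 1), 0.03)
  expect_equal(optimal_hydrolysis_time(0.03, 1e-4)$attachment_time_s, 9)
})

test_that("effective diffusion at a time scale follows the power law", {
  expect_equal(effective_D_at_timescale(1.5e-3, 1e-3, alpha = 0.4),
               1.5e-3 * (1e-3)^(-0.6))
  expect_equal(effective_D_at_timescale(1.5e-3, 1e-3, alpha = 0.4), 0.0946,
               tolerance = 0.01)
  expect_equal(effective_D_at_timescale(0.25e-3, 1e-3, alpha = 0.4), 0.0158,
               tolerance = 0.01)
  # the printed range (1.5-9) x 10^-2 um^2/s brackets both ends
  lo <- effective_D_at_timescale(0.25e-3, 1e-3, alpha = 0.4)
  hi <- effective_D_at_timescale(1.5e-3, 1e-3, alpha = 0.4)
  expect_gt(lo, 0.015)
  expect_lt(hi, 0.095)
  # alpha = 1 is the normal-diffusion identity
  expect_equal(effective_D_at_timescale(2e-3, 1e-3, alpha = 1), 2e-3)
})

test_that("filament length bounds follow the two geometries", {
  b <- filament_length_bounds(90)
  expect_equal(b$nucleoprotein_nm, 90 / 4.4 * 12)  # ~245 nm, quoted as 240
  expect_equal(b$nucleoprotein_nm, 245.45, tolerance = 1e-4)
  expect_equal(b$linear_nm, 90 * 6.4)              # ~580 nm
  expect_equal(filament_length_bounds(0)$nucleoprotein_nm, 0)
  expect_equal(filament_length_bounds(180)$linear_nm,
               2 * filament_length_bounds(90)$linear_nm)
})
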