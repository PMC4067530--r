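test_that("generators are reproducible from their seed", {
  a <- gen_locus_fluctuation(n_cells = 5, seed = 9)
  b <- gen_locus_fluctuation(n_cells = 5, seed = 9)
  expect_identical(a$data, b$data)
  c2 <- gen_locus_fluctuation(n_cells = 5, seed = 10)
  expect_false(identical(a$data, c2$data))
  m1 <- gen_multiphasic_two_spot(seed = 3)
  m2 <- gen_multiphasic_two_spot(seed = 3)
  expect_identical(m1$data, m2$data)
  expect_identical(m1$truth, m2$truth)
})

test_that("locus generator approaches iid Gaussian frames when D is large", {
  # frame interval >> relaxation time: lag-1 autocorrelation ~ 0
  g <- gen_locus_fluctuation(n_cells = 40, frame_s = 2, D = 0.01,
                             sigma_long = 0.06, sigma_short = 0.04, seed = 2)
  dev <- pool_deviations(g$data)
  per_cell <- split(dev$dx_um, dev$cell_id)
  ac1 <- mean(vapply(per_cell, function(v) {
    stats::cor(v[-1], v[-length(v)])
  }, numeric(1)))
  expect_lt(abs(ac1), 0.1)  # theory: exp(-D frame_s / sigma^2) ~ 0.004
})

test_that("multiphasic generator produces a recoverable run", {
  g <- gen_multiphasic_two_spot(seed = 11)
  linked <- link_two_spots(g$data)
  # distal trajectory = larger mean x
  mean_x <- tapply(linked$x_um, linked$traj, mean)
  distal <- linked[linked$traj == as.integer(names(which.max(mean_x))), ]
  ann <- detect_fast_phase(distal$t_s, distal$x_um)
  expect_true(ann$run_detected)
  expect_lte(abs(ann$run_start_idx - g$truth$run_start_frame), 2)
  expect_lte(abs(ann$run_end_idx - g$truth$run_end_frame), 2)
  m <- run_metrics(distal$t_s, distal$x_um, ann)
  expect_equal(m$run_length, g$truth$run_length_um, tolerance = 0.2)
  expect_equal(m$speed_nm_min, g$truth$speed_nm_min, tolerance = 0.25)
  # zero-speed fast phase: no run to detect
  g0 <- gen_multiphasic_two_spot(speed_nm_min = 0, seed = 12)
  linked0 <- link_two_spots(g0$data)
  mean_x0 <- tapply(linked0$x_um, linked0$traj, mean)
  distal0 <- linked0[linked0$traj ==
                       as.integer(names(which.max(mean_x0))), ]
  expect_false(detect_fast_phase(distal0$t_s, distal0$x_um)$run_detected)
  # doubling speed at fixed run duration is handled via run length
  g2 <- gen_multiphasic_two_spot(run_length_um = 2, seed = 13)
  expect_equal(g2$truth$run_period_s, 2 * g$truth$run_period_s)
})

test_that("short-axis displacements match across slow and fast phases", {
  # isotropic diffusion in both phases: same short-axis displacement law
  g <- gen_multiphasic_two_spot(seed = 21, loc_noise_sd = 0)
  linked <- link_two_spots(g$data)
  mean_x <- tapply(linked$x_um, linked$traj, mean)
  distal <- linked[linked$traj == as.integer(names(which.max(mean_x))), ]
  distal <- distal[order(distal$frame), ]
  slow <- which(distal$frame < g$truth$run_start_frame)
  fast <- which(distal$frame >= g$truth$run_start_frame &
                  distal$frame <= g$truth$run_end_frame)
  dy_slow <- diff(distal$y_um[slow])
  dy_fast <- diff(distal$y_um[fast])
  expect_gt(ks.test(dy_slow, dy_fast)$p.value, 0.01)
})

test_that("kinetics generators hit their analytic limits", {
  g <- gen_mm_kinetics(vmax = 120, K = 80, noise_frac = 0, seed = 1)
  fit <- fit_michaelis_menten(g$data$S, g$data$v)
  expect_equal(fit$vmax, 120, tolerance = 1e-6)
  expect_equal(fit$K, 80, tolerance = 1e-6)
  # zero-rate wells are flat
  tc0 <- gen_nadh_timecourse(rate_uM_hr = 0, noise_sd = 0, seed = 2)
  expect_equal(var(tc0$data$a340), 0)
  # time-course slope matches the implied rate
  tc <- gen_nadh_timecourse(rate_uM_hr = 60, nadh_standard = 500,
                            noise_sd = 1e-4, seed = 3)
  iv <- initial_velocity(tc$data$t_min, tc$data$a340)
  expect_equal(convert_to_rate(iv$slope, 500), 60, tolerance = 0.02)
})

test_that("K_DNA-scale recovery stays within 15% at 5% noise", {
  fits <- vapply(1:100, function(r) {
    g <- gen_mm_kinetics(vmax = 6.7, K = 0.15,
                         S = c(0.05, 0.1, 0.25, 0.5, 1, 2),
                         noise_frac = 0.05, seed = 200 + r)
    fit_michaelis_menten(g$data$S, g$data$v)$K
  }, numeric(1))
  expect_lt(abs(median(fits) - 0.15) / 0.15, 0.15)
})

test_that("profile and ellipse generators encode their ground truth", {
  g <- gen_segment_profile(focus_fraction = 0.8, seed = 1)
  expect_equal(partition_fraction(g$data$fluorescence, g$data$area), 0.8,
               tolerance = 1e-6)
  iso <- gen_elliptical_region(n_points = 2000, sd_major = 1, sd_minor = 1,
                               seed = 2)
  expect_equal(aspect_ratio(iso$data)$aspect_ratio, 1, tolerance = 0.1)
  tri <- gen_elliptical_region(n_points = 3000, sd_major = 3, sd_minor = 1,
                               seed = 3)
  expect_equal(aspect_ratio(tri$data)$aspect_ratio, 3, tolerance = 0.1)
})
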