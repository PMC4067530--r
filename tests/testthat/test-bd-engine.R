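test_that("identical seed and config reproduce identical trajectories", {
  cfg <- sim_config(model = "dna_relay", t_fin = 20, seed = 42L,
                    record_every = 100L)
  a <- run_model(cfg)
  b <- run_model(cfg)
  expect_identical(a$x_um, b$x_um)
  expect_identical(a$y_um, b$y_um)
  expect_identical(a$n_bound, b$n_bound)
  c2 <- run_model(cfg, seed = 43L)
  expect_false(identical(a$x_um, c2$x_um))
})

test_that("state populations always sum to n_ParA and geometry is respected", {
  for (model in c("diffusion_binding", "dna_relay")) {
    cfg <- sim_config(model = model, t_fin = 120, seed = 9L,
                      record_every = 200L)
    tr <- run_model(cfg)
    expect_true(all(tr$n_bound + tr$n_dna + tr$n_free == cfg$n_ParA))
    expect_true(all(tr$x_um >= 0 & tr$x_um <= cfg$x_finish))
    expect_true(all(abs(tr$y_um) <= cfg$w0 / 2))
    d <- attr(tr, "dimers")
    onchr <- d$state != 0  # free dimers have no meaningful position
    expect_true(all(d$x[onchr] >= 0 & d$x[onchr] <= cfg$l0))
    expect_true(all(abs(d$y[onchr]) <= cfg$w0 / 2))
  }
})

test_that("free-diffusion MSD slope recovers 2D per axis", {
  # wide virtual cell so boundaries are several SDs away over the run
  cfg <- sim_config(model = "diffusion", t_fin = 1000, dt = 0.005,
                    D_PC = 1e-3, l0 = 10, x0 = 5, x_finish = 9.5,
                    record_every = 200L, seed = 3L)
  tr <- run_model(cfg)  # 1-s cadence, 1000 frames
  lag1 <- diff(tr$x_um)
  n <- length(lag1)
  expect_lt(abs(mean(lag1^2) - 2 * cfg$D_PC * 1),
            3 * 2 * cfg$D_PC * sqrt(2 / n))
  # y axis is reflected within +-w0/2 and must stay bounded
  expect_true(all(abs(tr$y_um) <= cfg$w0 / 2))
})

test_that("compiled tether integrator passes the Boltzmann/KS check", {
  z <- tether_samples(1e5, D = 0.01, sigma_long = 0.06, sigma_short = 0.04,
                      dt = 0.002, spacing_s = 2, seed = 12L)
  expect_equal(sd(z[, 1]), 0.06, tolerance = 0.02)
  expect_equal(sd(z[, 2]), 0.04, tolerance = 0.02)
  expect_gt(ks.test(z[, 1], "pnorm", 0, 0.06)$p.value, 0.01)
  expect_gt(ks.test(z[, 2], "pnorm", 0, 0.04)$p.value, 0.01)
})

test_that("unbiased diffusion stays near its start over 600 s", {
  cfg <- sim_config(model = "diffusion", t_fin = 600, dt = 0.005,
                    n_runs = 50, seed = 21L, record_every = 2000L)
  ens <- run_ensemble(cfg)
  drift <- abs(ens$mean_x[length(ens$mean_x)] - cfg$x0)
  expect_lt(drift, 3 * sqrt(2 * cfg$D_PC * 600 / cfg$n_runs))
})

test_that("captured dimers release with the configured exponential dwell", {
  # k_cat = 0: a captured dimer never releases
  st <- list(t = 0, pc = c(0.8, 0),
             dimers = data.frame(x = 0.8, y = 0.02, eq_x = 0.8, eq_y = 0.02,
                                 state = "dna_bound", next_event = Inf),
             config = sim_config(model = "diffusion_binding", k_cat = 0))
  st <- update_bindings(st)
  expect_equal(st$dimers$state, "pc_bound")
  expect_equal(st$dimers$next_event, Inf)
  # k_cat > 0: scheduled dwells are Exp(1/k_cat) with mean 33.3 s
  set.seed(8)
  n <- 1e4
  k_cat <- 0.03
  st2 <- list(t = 0, pc = c(0.8, 0),
              dimers = data.frame(x = rep(0.8, n), y = 0, eq_x = 0.8,
                                  eq_y = 0, state = "dna_bound",
                                  next_event = Inf),
              config = sim_config(model = "diffusion_binding",
                                  k_cat = k_cat))
  st2 <- update_bindings(st2)
  dwell <- st2$dimers$next_event
  expect_true(all(st2$dimers$state == "pc_bound"))
  expect_lt(abs(mean(dwell) - 1 / k_cat), 3 * (1 / k_cat) / sqrt(n))
})

test_that("capture triggers exactly at disk overlap", {
  cfg <- sim_config(model = "diffusion_binding")
  mk <- function(dx) list(
    t = 0, pc = c(0, 0),
    dimers = data.frame(x = dx, y = 0, eq_x = dx, eq_y = 0,
                        state = "dna_bound", next_event = Inf),
    config = cfg)
  # R_PC + R_ParA = 0.052: 0.051 captures, boundary equality captures,
  # 0.053 does not
  expect_equal(update_bindings(mk(0.051))$dimers$state, "pc_bound")
  expect_equal(update_bindings(mk(cfg$R_PC + cfg$R_ParA))$dimers$state,
               "pc_bound")
  expect_equal(update_bindings(mk(0.053))$dimers$state, "dna_bound")
})

test_that("released dimers rebind ahead of the complex with a new tether", {
  set.seed(10)
  cfg <- sim_config(model = "dna_relay")
  st <- list(t = 100, pc = c(1.2, 0),
             dimers = data.frame(x = NA_real_, y = NA_real_, eq_x = NA_real_,
                                 eq_y = NA_real_, state = "free",
                                 next_event = 99),
             config = cfg)
  st <- update_bindings(st)
  expect_equal(st$dimers$state, "dna_bound")
  expect_gte(st$dimers$x, 1.2)
  expect_lte(st$dimers$x, cfg$l0)
  expect_equal(st$dimers$eq_x, st$dimers$x)
  expect_equal(st$dimers$eq_y, st$dimers$y)
})

test_that("R reference stepper and compiled engine agree statistically", {
  # pure diffusion: compare increment variance over 200 steps
  cfg <- sim_config(model = "diffusion", dt = 0.005, t_fin = 1)
  set.seed(31)
  st <- init_sim_state(cfg)
  xs <- numeric(200)
  for (i in 1:200) {
    st <- step_state(st)
    xs[i] <- st$pc[1]
  }
  inc_r <- diff(c(cfg$x0, xs))
  tr <- run_model(sim_config(model = "diffusion", dt = 0.005, t_fin = 1,
                             record_every = 1L, seed = 77L))
  inc_c <- diff(tr$x_um)
  v <- 2 * cfg$D_PC * cfg$dt
  expect_lt(abs(mean(inc_r^2) - v), 4 * v * sqrt(2 / 200))
  expect_lt(abs(mean(inc_c^2) - v), 4 * v * sqrt(2 / length(inc_c)))
})

test_that("dt stability precondition refuses to run", {
  expect_error(sim_config(dt = 0.05), "dt")
  cfg <- sim_config()
  cfg$dt <- 0.05  # corrupt after construction
  expect_error(run_model(cfg), "dt")
})

test_that("ensembles are summarised consistently", {
  cfg <- sim_config(model = "diffusion", t_fin = 60, n_runs = 3, seed = 5L,
                    record_every = 1000L)
  ens <- run_ensemble(cfg)
  # singleton ensemble reduces to run_model output
  e1 <- run_ensemble(sim_config(model = "diffusion", t_fin = 60, n_runs = 1,
                                seed = 5L, record_every = 1000L))
  tr1 <- run_model(sim_config(model = "diffusion", t_fin = 60, n_runs = 1,
                              seed = 5L, record_every = 1000L))
  expect_equal(e1$mean_x, tr1$x_um)
  # completion fraction is monotone non-decreasing and in [0, 1]
  expect_true(all(diff(ens$completion_fraction) >= 0))
  expect_true(all(ens$completion_fraction >= 0 &
                    ens$completion_fraction <= 1))
  # mean over runs consistent with per-run trajectories
  xs <- sapply(0:2, function(i)
    run_model(cfg, seed = cfg$seed + i)$x_um)
  expect_equal(ens$mean_x, rowMeans(xs))
})
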