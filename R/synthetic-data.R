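#' Synthetic chromosomal-locus fluctuation trajectories
#'
#' Per-cell trajectories of a locus fluctuating in an anisotropic harmonic
#' well, generated with the same compiled integrator as the simulation engine
#' (internal step `dt`, subsampled at the imaging frame interval). Defaults
#' reproduce the locus-tracking design: 641 cells imaged every 2 s for 180 s
#' with well SDs (0.06, 0.04) um and D = 0.01 um^2/s. Equilibrium points are
#' randomised per cell; optional Gaussian localization noise can be added.
#'
#' @param n_cells Number of cells.
#' @param frame_s Frame interval, s.
#' @param duration_s Trajectory duration, s.
#' @param sigma_long,sigma_short Well SDs, um.
#' @param D Locus diffusion coefficient, um^2/s.
#' @param dt Internal integrator step, s.
#' @param loc_noise_sd Localization noise SD, um (default 0: the target SDs
#'   are treated as the total observed spread).
#' @param seed RNG seed.
#' @return A list with `data` (data frame `cell_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`) and `truth` (the generating parameters).
#' @export
gen_locus_fluctuation <- function(n_cells = 641, frame_s = 2,
                                  duration_s = 180, sigma_long = 0.06,
                                  sigma_short = 0.04, D = 0.01, dt = 0.005,
                                  loc_noise_sd = 0, seed = 1L) {
  stopifnot(dt <= 0.1 * min(sigma_long, sigma_short)^2 / D)
  set.seed(seed)
  n_frames <- floor(duration_s / frame_s)
  rec <- as.integer(round(frame_s / dt))
  eq_x <- runif(n_cells, 1, 2)    # equilibrium points vary cell to cell
  eq_y <- runif(n_cells, -0.05, 0.05)
  x0 <- rnorm(n_cells, 0, sigma_long)   # stationary initial deviations
  y0 <- rnorm(n_cells, 0, sigma_short)
  parts <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    dev <- .tether_traj_cpp(n_frames, rec, dt, D, sigma_long, sigma_short,
                            x0[i], y0[i], as.double(seed + i))
    x <- eq_x[i] + dev[, 1]
    y <- eq_y[i] + dev[, 2]
    if (loc_noise_sd > 0) {
      x <- x + rnorm(n_frames, 0, loc_noise_sd)
      y <- y + rnorm(n_frames, 0, loc_noise_sd)
    }
    parts[[i]] <- data.frame(cell_id = i, frame = seq_len(n_frames),
                             t_s = seq_len(n_frames) * frame_s,
                             x_um = x, y_um = y)
  }
  list(data = do.call(rbind, parts),
       truth = list(sigma_long = sigma_long, sigma_short = sigma_short,
                    D = D, frame_s = frame_s, n_cells = n_cells,
                    loc_noise_sd = loc_noise_sd, seed = seed))
}

#' Synthetic free-diffusion trajectory
#'
#' A 1-D (or 2-D) pure random walk sampled at a fixed frame interval, for
#' validating displacement- and MSD-based diffusion estimators.
#'
#' @param n_frames Number of frames.
#' @param D Diffusion coefficient, um^2/s.
#' @param frame_s Frame interval, s.
#' @param ndim 1 or 2 dimensions.
#' @param x0 Starting coordinate(s).
#' @param loc_noise_sd Localization noise SD, um.
#' @param seed RNG seed.
#' @return A list with `data` (data frame `frame`, `t_s`, `x_um` [, `y_um`])
#'   and `truth`.
#' @export
gen_free_diffusion <- function(n_frames = 2000, D = 1e-4, frame_s = 20,
                               ndim = 1, x0 = 0, loc_noise_sd = 0,
                               seed = 1L) {
  set.seed(seed)
  step_sd <- sqrt(2 * D * frame_s)
  out <- data.frame(frame = seq_len(n_frames),
                    t_s = (seq_len(n_frames) - 1) * frame_s)
  out$x_um <- x0[1] + c(0, cumsum(rnorm(n_frames - 1, 0, step_sd))) +
    rnorm(n_frames, 0, loc_noise_sd)
  if (ndim == 2) {
    y0 <- if (length(x0) > 1) x0[2] else 0
    out$y_um <- y0 + c(0, cumsum(rnorm(n_frames - 1, 0, step_sd))) +
      rnorm(n_frames, 0, loc_noise_sd)
  }
  list(data = out, truth = list(D = D, frame_s = frame_s,
                                loc_noise_sd = loc_noise_sd, seed = seed))
}

#' Synthetic two-spot multiphasic segregation record
#'
#' Emulates a spot-tracking table of a segregating cell: a proximal complex
#' confined near the old pole and a distal complex that moves through a
#' diffusive slow phase, a directed fast phase (constant velocity plus
#' diffusion), and a confined anchored phase. Defaults follow the measured
#' population means: run length 1.0 um at 220 nm/min, 20-s frames, 20-nm
#' localization noise. Ground-truth changepoints are returned alongside.
#'
#' @param slow_s,anchored_s Durations of the slow and anchored phases, s.
#' @param run_length_um Fast-phase run length, um.
#' @param speed_nm_min Fast-phase speed, nm/min.
#' @param D_slow Slow/anchored-phase diffusion coefficient, um^2/s.
#' @param anchor_sd Confinement SD in the anchored phase, um.
#' @param frame_s Frame interval, s.
#' @param x0 Distal-complex position at duplication, um.
#' @param x_prox Proximal-complex anchor position, um.
#' @param cell_l,cell_w Cell length and width, um.
#' @param loc_noise_sd Localization noise SD, um.
#' @param seed RNG seed.
#' @return A list with `data` (spot table `cell_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, unlabeled, two rows per frame) and `truth` (changepoint frames
#'   `run_start_frame`, `run_end_frame`, plus the generating parameters).
#' @export
gen_multiphasic_two_spot <- function(slow_s = 300, anchored_s = 300,
                                     run_length_um = 1.0,
                                     speed_nm_min = 220, D_slow = 1e-4,
                                     anchor_sd = 0.02, frame_s = 20,
                                     x0 = 0.8, x_prox = 0.3,
                                     cell_l = 2.6, cell_w = 0.4,
                                     loc_noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  speed <- speed_nm_min / 1000 / 60  # um/s
  if (speed <= 0 || run_length_um <= 0) {
    speed <- 0
    run_s <- 0
  } else {
    run_s <- run_length_um / speed
  }
  n_slow <- round(slow_s / frame_s)
  n_run <- round(run_s / frame_s)
  n_anch <- round(anchored_s / frame_s)
  n <- n_slow + n_run + n_anch
  t_s <- (seq_len(n) - 1) * frame_s
  step_sd <- sqrt(2 * D_slow * frame_s)

  # distal complex, long axis
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) {
    drift <- if (i > n_slow && i <= n_slow + n_run) speed * frame_s else 0
    noise <- if (i > n_slow + n_run) 0 else rnorm(1, 0, step_sd)
    x[i] <- x[i - 1] + drift + noise
  }
  anchor_x <- x[n_slow + n_run]
  if (n_anch > 0) {
    idx <- (n_slow + n_run + 1):n
    x[idx] <- anchor_x + rnorm(length(idx), 0, anchor_sd)
  }
  y_dist <- cumsum(c(0, rnorm(n - 1, 0, step_sd)))
  y_dist <- reflect_coord(y_dist, -cell_w / 2, cell_w / 2)

  # proximal complex: confined near its anchor point
  x_p <- x_prox + rnorm(n, 0, anchor_sd * 2)
  y_p <- rnorm(n, 0, anchor_sd * 2)

  noisy <- function(v) v + rnorm(length(v), 0, loc_noise_sd)
  spots <- rbind(
    data.frame(cell_id = 1L, frame = seq_len(n), t_s = t_s,
               x_um = noisy(x), y_um = noisy(y_dist)),
    data.frame(cell_id = 1L, frame = seq_len(n), t_s = t_s,
               x_um = noisy(x_p), y_um = noisy(y_p)))
  spots <- spots[order(spots$frame), ]
  rownames(spots) <- NULL
  list(data = spots,
       truth = list(run_start_frame = n_slow + 1,
                    run_end_frame = n_slow + n_run,
                    run_length_um = run_length_um, run_period_s = run_s,
                    speed_nm_min = speed_nm_min, frame_s = frame_s,
                    D_slow = D_slow, loc_noise_sd = loc_noise_sd,
                    seed = seed))
}

#' Synthetic Michaelis-Menten substrate-dependence table
#'
#' Specific activities on a substrate grid with multiplicative Gaussian
#' noise, for parameter-recovery studies of the kinetics fits.
#'
#' @param vmax True Vmax (k_cat), /hr.
#' @param K True half-saturation constant (substrate units).
#' @param S Substrate grid.
#' @param noise_frac Multiplicative noise SD as a fraction of the mean.
#' @param replicates Replicates per grid point.
#' @param seed RNG seed.
#' @return A list with `data` (data frame `S`, `v`) and `truth`.
#' @export
gen_mm_kinetics <- function(vmax = 120, K = 80,
                            S = c(10, 20, 40, 80, 160, 320),
                            noise_frac = 0.05, replicates = 1, seed = 1L) {
  set.seed(seed)
  Sg <- rep(S, each = replicates)
  mu <- vmax * Sg / (K + Sg)
  v <- pmax(0, mu * (1 + rnorm(length(Sg), 0, noise_frac)))
  list(data = data.frame(S = Sg, v = v),
       truth = list(vmax = vmax, K = K, noise_frac = noise_frac,
                    seed = seed))
}

#' Synthetic NADH-coupled absorbance time course
#'
#' Linear A340 decline implied by an ADP production rate through the NADH
#' standard factor, with additive Gaussian noise.
#'
#' @param rate_uM_hr ADP production rate, uM/hr.
#' @param nadh_standard uM NADH per absorbance unit.
#' @param duration_min Duration, min (1-min sampling).
#' @param a0 Initial absorbance.
#' @param noise_sd Additive absorbance noise SD.
#' @param seed RNG seed.
#' @return A list with `data` (data frame `t_min`, `a340`) and `truth`
#'   (including the implied `slope` in absorbance/min).
#' @export
gen_nadh_timecourse <- function(rate_uM_hr = 60, nadh_standard = 500,
                                duration_min = 30, a0 = 1.0,
                                noise_sd = 1e-4, seed = 1L) {
  set.seed(seed)
  t_min <- 0:duration_min
  slope <- -rate_uM_hr / nadh_standard / 60  # absorbance per min
  a340 <- a0 + slope * t_min + rnorm(length(t_min), 0, noise_sd)
  list(data = data.frame(t_min = t_min, a340 = a340),
       truth = list(rate_uM_hr = rate_uM_hr, slope = slope,
                    nadh_standard = nadh_standard, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic per-cell segment fluorescence profile
#'
#' One bright focus on a diffuse background: a fraction `focus_fraction` of
#' the total signal is placed in one segment, the rest spread uniformly.
#'
#' @param n_segments Number of segments along the cell.
#' @param focus_fraction Fraction of total signal in the focus.
#' @param total Total fluorescence.
#' @param focus_segment Index of the focus segment (default middle).
#' @param noise_frac Multiplicative per-segment noise SD.
#' @param seed RNG seed.
#' @return A list with `data` (data frame `segment`, `fluorescence`, `area`)
#'   and `truth`.
#' @export
gen_segment_profile <- function(n_segments = 20, focus_fraction = 0.8,
                                total = 1000,
                                focus_segment = ceiling(n_segments / 2),
                                noise_frac = 0, seed = 1L) {
  set.seed(seed)
  f <- rep(total * (1 - focus_fraction) / n_segments, n_segments)
  f[focus_segment] <- f[focus_segment] + total * focus_fraction
  if (noise_frac > 0) f <- pmax(0, f * (1 + rnorm(n_segments, 0, noise_frac)))
  list(data = data.frame(segment = seq_len(n_segments), fluorescence = f,
                         area = rep(1, n_segments)),
       truth = list(focus_fraction = focus_fraction,
                    focus_segment = focus_segment, seed = seed))
}

#' Synthetic elliptical point cloud
#'
#' Gaussian point cloud with chosen axis SDs and orientation, standing in
#' for the localised signal of a (possibly stretched) partition complex.
#'
#' @param n_points Number of points.
#' @param sd_major,sd_minor Axis SDs (input units).
#' @param angle_rad Rotation of the major axis.
#' @param center Length-2 centre.
#' @param seed RNG seed.
#' @return A list with `data` (two-column matrix) and `truth` (including the
#'   population aspect ratio `sd_major/sd_minor`).
#' @export
gen_elliptical_region <- function(n_points = 500, sd_major = 3, sd_minor = 1,
                                  angle_rad = 0, center = c(0, 0),
                                  seed = 1L) {
  set.seed(seed)
  u <- cbind(rnorm(n_points, 0, sd_major), rnorm(n_points, 0, sd_minor))
  rot <- matrix(c(cos(angle_rad), sin(angle_rad),
                  -sin(angle_rad), cos(angle_rad)), 2, 2)
  pts <- sweep(u %*% t(rot), 2, center, `+`)
  colnames(pts) <- c("x", "y")
  list(data = pts,
       truth = list(aspect_ratio = sd_major / sd_minor, sd_major = sd_major,
                    sd_minor = sd_minor, angle_rad = angle_rad, seed = seed))
}
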