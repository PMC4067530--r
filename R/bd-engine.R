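#' Run one Brownian-dynamics trajectory
#'
#' Simulates the partition complex (and, for the binding models, the ParA-ATP
#' dimer population) under the configured mechanism until `t_fin` or until the
#' complex crosses `x_finish`, whichever comes first. The compiled engine is a
#' pure function of `(config, seed)`: identical inputs reproduce identical
#' trajectories.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An object of class `bd_trajectory`: a data frame with columns
#'   `t_s`, `x_um`, `y_um`, `n_bound` (ParA dimers attached to the complex),
#'   `n_dna`, `n_free`, with attributes `crossed` (logical), `crossing_time`
#'   (s or `NA`), `dimers` (final agent states) and `config`.
#' @examples
#' cfg <- sim_config(model = "diffusion", t_fin = 50, record_every = 1000)
#' traj <- run_model(cfg)
#' head(traj)
#' @export
run_model <- function(config, seed = config$seed) {
  validate_sim_config(config)
  cc <- unclass(config)
  cc$model_code <- .model_code(config$model)
  res <- .bd_run_cpp(cc, as.double(seed))
  out <- data.frame(t_s = res$t, x_um = res$x, y_um = res$y,
                    n_bound = res$n_bound, n_dna = res$n_dna,
                    n_free = res$n_free)
  attr(out, "crossed") <- res$crossed
  attr(out, "crossing_time") <- res$crossing_time
  attr(out, "dimers") <- res$dimers
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("bd_trajectory", "data.frame")
  out
}

#' Run an ensemble of trajectories
#'
#' Runs `config$n_runs` independent trajectories (run `i` uses seed
#' `config$seed + i - 1`) and summarises them on the common recording grid.
#' Runs that cross `x_finish` early are held at `x_finish` for the
#' mean-trajectory average and contribute to the completion fraction from
#' their crossing time onward.
#'
#' @param config A [sim_config()].
#' @param n_runs Optional override of `config$n_runs`.
#' @return An object of class `bd_ensemble`: a list with `times` (s),
#'   `mean_x` (um), `completion_fraction` (non-decreasing, in `[0, 1]`),
#'   `crossing_times` (s, `NA` for unfinished runs), `final_x`, `n_runs`,
#'   `config`.
#' @export
run_ensemble <- function(config, n_runs = config$n_runs) {
  validate_sim_config(config)
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1)
  times <- seq(0, config$t_fin, by = config$dt * config$record_every)
  sum_x <- numeric(length(times))
  crossing_times <- rep(NA_real_, n_runs)
  final_x <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    tr <- run_model(config, seed = config$seed + i - 1L)
    xi <- rep(NA_real_, length(times))
    n_obs <- min(nrow(tr), length(times))
    xi[seq_len(n_obs)] <- tr$x_um[seq_len(n_obs)]
    if (isTRUE(attr(tr, "crossed"))) {
      crossing_times[i] <- attr(tr, "crossing_time")
      xi[is.na(xi)] <- config$x_finish  # held at x_finish after crossing
    } else {
      xi[is.na(xi)] <- tr$x_um[nrow(tr)]
    }
    sum_x <- sum_x + xi
    final_x[i] <- tr$x_um[nrow(tr)]
  }
  cf <- vapply(times, function(t) mean(!is.na(crossing_times) &
                                         crossing_times <= t), numeric(1))
  out <- list(times = times, mean_x = sum_x / n_runs,
              completion_fraction = cf, crossing_times = crossing_times,
              final_x = final_x, n_runs = n_runs, config = config)
  class(out) <- "bd_ensemble"
  out
}

#' @export
print.bd_ensemble <- function(x, ...) {
  cat(sprintf("bd_ensemble: %d %s runs, t_fin = %g s\n",
              x$n_runs, x$config$model, x$config$t_fin))
  cat(sprintf("  completed: %d/%d (fraction %.3f)\n",
              sum(!is.na(x$crossing_times)), x$n_runs,
              mean(!is.na(x$crossing_times))))
  if (any(!is.na(x$crossing_times)))
    cat(sprintf("  median crossing time: %.0f s\n",
                median(x$crossing_times, na.rm = TRUE)))
  cat(sprintf("  mean final x: %.3f um (start %.2f um)\n",
              mean(x$mean_x[length(x$mean_x)]), x$config$x0))
  invisible(x)
}

#' @export
summary.bd_ensemble <- function(object, ...) {
  data.frame(
    model = object$config$model,
    n_runs = object$n_runs,
    completed = sum(!is.na(object$crossing_times)),
    completion_fraction = mean(!is.na(object$crossing_times)),
    mean_final_x_um = object$mean_x[length(object$mean_x)],
    net_displacement_um =
      object$mean_x[length(object$mean_x)] - object$config$x0)
}

#' Decorrelated stationary samples of a harmonically tethered particle
#'
#' Runs the compiled tether integrator (the same update used for DNA-bound
#' ParA dimers) and returns positional deviations recorded every
#' `spacing_s` seconds, starting from a stationary draw.
#'
#' @param n_samples Number of recorded samples.
#' @param D Diffusion coefficient, um^2/s.
#' @param sigma_long,sigma_short Well SDs per axis, um.
#' @param dt Integrator step, s.
#' @param spacing_s Recording interval, s (choose several relaxation times
#'   `sigma^2/D` for effectively independent samples).
#' @param seed RNG seed.
#' @return Matrix with columns `x`, `y` of deviations from the tether point.
#' @export
tether_samples <- function(n_samples, D = 1e-2, sigma_long = 0.06,
                           sigma_short = 0.04, dt = 0.002,
                           spacing_s = 2, seed = 1L) {
  set.seed(seed)
  x0 <- rnorm(1, 0, sigma_long)
  y0 <- rnorm(1, 0, sigma_short)
  m <- .tether_traj_cpp(as.integer(n_samples),
                        as.integer(round(spacing_s / dt)), dt, D,
                        sigma_long, sigma_short, x0, y0, as.double(seed))
  colnames(m) <- c("x", "y")
  m
}
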