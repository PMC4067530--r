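#' Simulation configuration
#'
#' Builds and validates the parameter set of the Brownian-dynamics engine.
#' Defaults are the default simulation parameters of the study: a 2.6 x 0.4 um
#' reflective cell, complex starting at (0.8, 0) um, 90 DNA-bound ParA-ATP
#' dimers, ParB-stimulated hydrolysis rate 0.03 /s, mean DNA-rebinding time
#' 1/0.03 s, D_PC = 1e-4 um^2/s, D_A = 1e-2 um^2/s and locus-fluctuation SDs
#' (0.06, 0.04) um defining the tether spring constants via k_sp/kT = 1/sigma^2.
#'
#' @param dt Time step, s.
#' @param t_fin Maximum simulated time, s.
#' @param n_runs Ensemble size used by [run_ensemble()].
#' @param l0,w0 Cell length and width, um.
#' @param x0,y0 Initial partition-complex coordinates, um (old pole at x = 0).
#' @param x_start,x_finish Fast-phase analysis window bounds, um. Crossing
#'   `x_finish` terminates a run (absorbing).
#' @param R_PC,R_ParA Disk radii of the partition complex and of a ParA dimer,
#'   um.
#' @param n_ParA Number of ParA-ATP dimers.
#' @param k_cat ParB-stimulated ATP-hydrolysis rate, /s; sets the mean tether
#'   lifetime 1/k_cat. `k_cat = 0` means attached dimers never release.
#' @param tau_db Mean free-to-DNA-bound rebinding time, s.
#' @param D_PC,D_A Diffusion coefficients of the partition complex and of a
#'   DNA-bound ParA dimer, um^2/s.
#' @param sigma_long,sigma_short Positional-fluctuation SDs of a DNA-bound
#'   dimer along the long and short cell axes, um.
#' @param model One of `"diffusion"`, `"diffusion_binding"`, `"dna_relay"`.
#' @param seed Master RNG seed (integer). Run `i` of an ensemble uses
#'   `seed + i - 1`.
#' @param record_every Output decimation in steps.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(model = "dna_relay", n_runs = 4, t_fin = 100)
#' cfg$k_cat
#' @export
sim_config <- function(dt = 0.001, t_fin = 2000, n_runs = 1024,
                       l0 = 2.6, w0 = 0.4, x0 = 0.8, y0 = 0,
                       x_start = 1.5, x_finish = 2.5,
                       R_PC = 0.05, R_ParA = 0.002, n_ParA = 90,
                       k_cat = 0.03, tau_db = 1 / 0.03,
                       D_PC = 1e-4, D_A = 1e-2,
                       sigma_long = 0.06, sigma_short = 0.04,
                       model = c("diffusion", "diffusion_binding", "dna_relay"),
                       seed = 1L, record_every = 1000L) {
  model <- match.arg(model)
  cfg <- list(dt = dt, t_fin = t_fin, n_runs = as.integer(n_runs),
              l0 = l0, w0 = w0, x0 = x0, y0 = y0,
              x_start = x_start, x_finish = x_finish,
              R_PC = R_PC, R_ParA = R_ParA, n_ParA = as.integer(n_ParA),
              k_cat = k_cat, tau_db = tau_db, D_PC = D_PC, D_A = D_A,
              sigma_long = sigma_long, sigma_short = sigma_short,
              model = model, seed = as.integer(seed),
              record_every = as.integer(record_every))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks positivity of all lengths, times, rates and diffusivities, geometric
#' consistency of the initial position and analysis window, and the time-step
#' stability condition `dt <= 0.1 * min(sigma^2) / D_A` required for accurate
#' integration of the harmonic tether dynamics.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; errors name the offending key.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!isTRUE(ok)) stop("invalid `", key, "`: ", msg, call. = FALSE)
  }
  pos <- c("dt", "t_fin", "l0", "w0", "R_PC", "R_ParA", "tau_db",
           "D_PC", "D_A", "sigma_long", "sigma_short")
  for (key in pos) {
    chk(is.numeric(cfg[[key]]) && length(cfg[[key]]) == 1 &&
          is.finite(cfg[[key]]) && cfg[[key]] > 0,
        key, "must be a single positive finite number")
  }
  chk(cfg$k_cat >= 0, "k_cat", "must be non-negative")
  chk(cfg$n_ParA >= 0, "n_ParA", "must be non-negative")
  chk(cfg$n_runs >= 1, "n_runs", "must be at least 1")
  chk(cfg$record_every >= 1, "record_every", "must be at least 1")
  chk(cfg$x0 >= 0 && cfg$x0 <= cfg$l0, "x0", "must lie in [0, l0]")
  chk(abs(cfg$y0) <= cfg$w0 / 2, "y0", "must lie in [-w0/2, w0/2]")
  chk(cfg$x_start < cfg$x_finish, "x_start", "must be < x_finish")
  chk(cfg$x_finish <= cfg$l0, "x_finish", "must be <= l0")
  chk(cfg$R_ParA < cfg$R_PC, "R_ParA", "must be < R_PC")
  dt_max <- 0.1 * min(cfg$sigma_long, cfg$sigma_short)^2 / cfg$D_A
  chk(cfg$dt <= dt_max, "dt",
      sprintf("must be <= 0.1 * min(sigma^2) / D_A = %.4g s for stable tether dynamics",
              dt_max))
  chk(cfg$model %in% c("diffusion", "diffusion_binding", "dna_relay"),
      "model", "unknown model variant")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Brownian-dynamics configuration (", x$model, ")\n", sep = "")
  cat(sprintf("  cell %.2f x %.2f um, start (%.2f, %.2f), finish at x = %.2f um\n",
              x$l0, x$w0, x$x0, x$y0, x$x_finish))
  cat(sprintf("  dt = %g s, t_fin = %g s, n_runs = %d, seed = %d\n",
              x$dt, x$t_fin, x$n_runs, x$seed))
  cat(sprintf("  n_ParA = %d, k_cat = %g /s, tau_db = %g s\n",
              x$n_ParA, x$k_cat, x$tau_db))
  cat(sprintf("  D_PC = %g, D_A = %g um^2/s, sigma = (%g, %g) um\n",
              x$D_PC, x$D_A, x$sigma_long, x$sigma_short))
  invisible(x)
}

.model_code <- function(model) {
  match(model, c("diffusion", "diffusion_binding", "dna_relay"))
}
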