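#' Pool positional deviations of chromosomal-locus trajectories
#'
#' Subtracts each trajectory's own mean position per axis (removing
#' cell-to-cell variability in equilibrium position) and pools the deviations
#' across cells. Trajectories shorter than `min_frames` are excluded.
#'
#' @param traj Data frame with columns `cell_id`, `x_um`, `y_um`.
#' @param min_frames Minimum trajectory length (frames); default 5.
#' @return Data frame with columns `cell_id`, `dx_um`, `dy_um`; the number of
#'   excluded trajectories is attached as attribute `n_excluded`.
#' @export
pool_deviations <- function(traj, min_frames = 5) {
  stopifnot(all(c("cell_id", "x_um", "y_um") %in% names(traj)))
  parts <- split(traj, traj$cell_id)
  keep <- vapply(parts, nrow, integer(1)) >= min_frames
  if (any(!keep))
    message(sum(!keep), " trajectories shorter than ", min_frames,
            " frames excluded")
  pooled <- do.call(rbind, lapply(parts[keep], function(p) {
    data.frame(cell_id = p$cell_id,
               dx_um = p$x_um - mean(p$x_um),
               dy_um = p$y_um - mean(p$y_um))
  }))
  rownames(pooled) <- NULL
  attr(pooled, "n_excluded") <- sum(!keep)
  pooled
}

#' Fit an asymmetric (per-axis) zero-mean Gaussian to pooled deviations
#'
#' The stationary distribution of a locus in an anisotropic harmonic well is
#' a zero-mean Gaussian per axis; the per-axis SDs define the effective
#' spring constants via `k_sp/kT = 1/sigma^2`. Two fitting routes are
#' offered: maximum likelihood (the ML sigma of a zero-mean Gaussian is the
#' root mean square deviation) and least squares on a binned histogram.
#'
#' @param deviations Data frame from [pool_deviations()] (columns `dx_um`,
#'   `dy_um`), or a two-column matrix.
#' @param method `"mle"` (default) or `"binned"`.
#' @param bins Histogram bins for `method = "binned"`.
#' @param min_n Minimum pooled points (default 100).
#' @return A list (`fluctuation_fit`) with `sigma_long`, `sigma_short` (um),
#'   `sigma_long_se`, `sigma_short_se`, `n_points`, `method`.
#' @export
fit_asymmetric_gaussian <- function(deviations, method = c("mle", "binned"),
                                    bins = 41, min_n = 100) {
  method <- match.arg(method)
  if (is.data.frame(deviations)) {
    m <- cbind(deviations$dx_um, deviations$dy_um)
  } else {
    m <- as.matrix(deviations)
  }
  if (anyNA(m) || any(!is.finite(m)))
    stop("non-finite deviations", call. = FALSE)
  n <- nrow(m)
  if (n < min_n) stop("need at least ", min_n, " pooled points", call. = FALSE)

  fit_axis <- function(d) {
    if (method == "mle") {
      s <- sqrt(mean(d^2))
      list(sigma = s, se = s / sqrt(2 * n))
    } else {
      h <- graphics::hist(d, breaks = bins, plot = FALSE)
      df <- data.frame(x = h$mids, dens = h$density)
      fit <- nls(dens ~ 1 / (s * sqrt(2 * pi)) * exp(-x^2 / (2 * s^2)),
                 data = df, start = list(s = sd(d)))
      list(sigma = unname(coef(fit)["s"]),
           se = summary(fit)$coefficients["s", 2])
    }
  }
  fx <- fit_axis(m[, 1])
  fy <- fit_axis(m[, 2])
  list(sigma_long = fx$sigma, sigma_short = fy$sigma,
       sigma_long_se = fx$se, sigma_short_se = fy$se,
       n_points = n, method = method)
}

#' Convert a fluctuation SD to an effective spring constant
#'
#' `k_sp/kT = 1/sigma^2`; the absolute stiffness is `k_sp = kT/sigma^2`.
#' Only the ratio enters the dynamics; temperature matters solely for
#' reporting forces in pN.
#'
#' @param sigma Fluctuation SD, um.
#' @param temperature Absolute temperature, K.
#' @return A list (`spring_constants`) with `k_over_kT_um2` (um^-2),
#'   `k_pN_per_um`, `k_pN_per_nm`, `temperature`.
#' @examples
#' sigma_to_kspring(0.064)  # ~0.001 pN/nm
#' @export
sigma_to_kspring <- function(sigma, temperature = 303) {
  stopifnot(sigma > 0)
  k_over_kT <- 1 / sigma^2
  k_um <- kT(temperature) * k_over_kT
  list(k_over_kT_um2 = k_over_kT, k_pN_per_um = k_um,
       k_pN_per_nm = k_um / 1000, temperature = temperature)
}

#' Drag-force estimate of the translocating complex
#'
#' `F = v kT / D`: the force needed to move a particle of diffusion
#' coefficient `D` at velocity `v` through a viscous medium (mobility
#' `mu = D/kT`).
#'
#' @param v Velocity, um/s.
#' @param D Diffusion coefficient, um^2/s.
#' @param temperature Absolute temperature, K.
#' @return A list (`force_estimate`) with `force_pN`, `formula = "drag"` and
#'   the inputs.
#' @examples
#' drag_force(0.003, 1e-4)  # ~0.1 pN
#' @export
drag_force <- function(v, D, temperature = 303) {
  stopifnot(v >= 0, D > 0)
  list(force_pN = v * kT(temperature) / D, formula = "drag",
       inputs = list(v = v, D = D, temperature = temperature))
}

#' Characteristic elastic force of a tethered locus
#'
#' `F = k_sp sigma`: the typical force exerted by a harmonic tether displaced
#' by one fluctuation SD.
#'
#' @param k_sp Spring constant, pN/nm.
#' @param sigma Displacement, nm.
#' @return A list (`force_estimate`) with `force_pN`, `formula = "elastic"`
#'   and the inputs.
#' @examples
#' elastic_force(0.001, 60)  # 0.06 pN
#' @export
elastic_force <- function(k_sp, sigma) {
  stopifnot(k_sp >= 0, sigma >= 0)
  list(force_pN = k_sp * sigma, formula = "elastic",
       inputs = list(k_sp = k_sp, sigma = sigma))
}

#' Optimal tether attachment time and hydrolysis rate
#'
#' The time for the complex to relax to a tether's equilibrium point is
#' `dt = kT / (D k_sp) = sigma^2 / D`; releasing exactly then maximises the
#' use of the elastic force, so the optimal hydrolysis rate is its inverse.
#'
#' @param sigma Long-axis fluctuation SD, um.
#' @param D Partition-complex diffusion coefficient, um^2/s.
#' @return A list with `attachment_time_s` and `rate_per_s`.
#' @examples
#' optimal_hydrolysis_time(0.06, 1e-4)  # 36 s, ~0.03 /s
#' @export
optimal_hydrolysis_time <- function(sigma, D) {
  stopifnot(sigma > 0, D > 0)
  dt <- sigma^2 / D
  list(attachment_time_s = dt, rate_per_s = 1 / dt)
}

#' Effective diffusion coefficient at a chosen time scale
#'
#' Chromosomal loci show subdiffusion with a time-dependent (generalized)
#' diffusion coefficient `D(t) = D_app t^(alpha - 1)`; evaluating it at the
#' integrator time step yields the effective normal-diffusion coefficient
#' used for DNA-bound dimers.
#'
#' @param D_app Apparent (generalized) diffusion coefficient, um^2 s^-alpha.
#' @param dt Time scale of interest, s.
#' @param alpha Anomalous-diffusion exponent in (0, 1]; `alpha = 1` recovers
#'   `D = D_app`.
#' @return Effective D, um^2/s.
#' @examples
#' effective_D_at_timescale(1.5e-3, 1e-3, alpha = 0.4)  # ~0.095
#' @export
effective_D_at_timescale <- function(D_app, dt, alpha = 0.4) {
  stopifnot(D_app > 0, dt > 0, alpha > 0, alpha <= 1)
  D_app * dt^(alpha - 1)
}

#' Upper bounds on the length of a hypothetical ParA filament
#'
#' Two geometric bounds from the cellular dimer count: a nucleoprotein
#' filament packing `dimers_per_pitch` dimers per `pitch_nm` of helix, and a
#' bare linear polymer of one dimer of `unit_nm` per subunit along its
#' longest axis.
#'
#' @param n_dimers Number of ParA dimers per cell.
#' @param dimers_per_pitch Dimers per helical pitch (default 4.4).
#' @param pitch_nm Helical pitch, nm (default 12).
#' @param unit_nm Dimer unit length along the polymerisation axis, nm
#'   (default 6.4).
#' @return A list with `nucleoprotein_nm` and `linear_nm`.
#' @examples
#' filament_length_bounds(90)  # ~245 nm and ~580 nm
#' @export
filament_length_bounds <- function(n_dimers, dimers_per_pitch = 4.4,
                                   pitch_nm = 12, unit_nm = 6.4) {
  stopifnot(n_dimers >= 0, dimers_per_pitch > 0, pitch_nm > 0, unit_nm > 0)
  list(nucleoprotein_nm = n_dimers / dimers_per_pitch * pitch_nm,
       linear_nm = n_dimers * unit_nm)
}
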