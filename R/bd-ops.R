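#' Correlated Gaussian noise pair of the second-order integrator
#'
#' Draws the jointly Gaussian pair (R0, R1) entering the second-order
#' Brownian-dynamics update: zero means, `Var(R0) = 2 D dt`,
#' `Var(R1) = (2/3) D dt^3`, `Cov(R0, R1) = D dt^2`. R1 is drawn
#' conditionally on R0 as `N((dt/2) R0, D dt^3 / 6)`.
#'
#' @param n Number of pairs.
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Time step, s.
#' @return A numeric matrix with columns `R0` (um) and `R1` (um s).
#' @examples
#' z <- sample_correlated_noise(1000, D = 1e-4, dt = 1e-3)
#' cov(z)
#' @export
sample_correlated_noise <- function(n, D, dt) {
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  r0 <- sqrt(2 * D * dt) * rnorm(n)
  r1 <- dt / 2 * r0 + sqrt(D * dt^3 / 6) * rnorm(n)
  cbind(R0 = r0, R1 = r1)
}

#' Harmonic restoring force of a chromosomal tether
#'
#' Axis-wise elastic force pulling a particle toward its tether equilibrium
#' point, with spring constants parameterised by the positional-fluctuation
#' SDs: `k_sp/kT = 1/sigma^2` per axis. The force opposes the displacement
#' (the restoring convention), and the derivative dF/dx is `-k_sp` per axis.
#'
#' @param position,eq_point Numeric length-2 vectors (x, y), um. Vectorised:
#'   two-column matrices of positions are accepted.
#' @param k_over_kT Length-2 vector `(1/sigma_long^2, 1/sigma_short^2)`, um^-2.
#' @param temperature Absolute temperature, K (only scales the reported force
#'   to pN; the dynamics depend on `k_over_kT` alone).
#' @return A list with `force` (pN, same shape as `position`) and `deriv`
#'   (dF/dx per axis, pN/um).
#' @examples
#' spring_force(c(0.86, 0), c(0.8, 0), k_over_kT = c(1 / 0.06^2, 1 / 0.04^2))
#' @export
spring_force <- function(position, eq_point, k_over_kT, temperature = 303) {
  kt <- kT(temperature)
  k <- kt * k_over_kT  # pN/um per axis
  pos <- rbind(position)
  eq <- rbind(eq_point)
  f <- sweep(-(pos - eq), 2, k, `*`)
  if (is.null(dim(position))) f <- drop(f)
  list(force = f, deriv = -k)
}

#' One axis-wise step of the second-order Brownian-dynamics update
#'
#' Advances a coordinate by
#' `x + R0 + (D/kT) F dt + (D^2 / 2 (kT)^2) F F' dt^2 + (D/kT) F' R1`.
#' With `force = 0` the update reduces to the free-diffusion increment R0.
#' Vectorised over `x` (one fresh noise pair per element unless `noise` is
#' supplied).
#'
#' @param x Coordinate(s), um.
#' @param force Force F, pN (recycled).
#' @param force_deriv Derivative F' = dF/dx, pN/um (recycled).
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Time step, s.
#' @param temperature Absolute temperature, K.
#' @param noise Optional matrix from [sample_correlated_noise()] with
#'   `length(x)` rows; drawn fresh when `NULL`.
#' @return Updated coordinate(s), um.
#' @export
bd_step <- function(x, force, force_deriv, D, dt, temperature = 303,
                    noise = NULL) {
  if (is.null(noise)) noise <- sample_correlated_noise(length(x), D, dt)
  kt <- kT(temperature)
  x + noise[, 1] + (D / kt) * force * dt +
    D^2 / (2 * kt^2) * force * force_deriv * dt^2 +
    (D / kt) * force_deriv * noise[, 2]
}

#' Sample a ParA DNA-rebinding position along the long axis
#'
#' Rebinding positions follow a linearly increasing density between the
#' current partition-complex position and the new pole,
#' `P(x) = 2 (x - x_pc) / (l - x_pc)^2` on `(x_pc, l)`, emulating the
#' intracellular ParA-ATP dimer gradient. Implemented by inverse CDF:
#' `x = x_pc + (l - x_pc) * sqrt(u)`.
#'
#' @param n Number of draws.
#' @param x_pc Current partition-complex long-axis position, um.
#' @param l Cell length, um.
#' @param u Optional uniform variates (for deterministic checks).
#' @return Long-axis positions, um.
#' @examples
#' sample_rebinding_x(3, x_pc = 0.8, l = 2.6, u = c(0, 0.25, 1))
#' @export
sample_rebinding_x <- function(n, x_pc, l, u = NULL) {
  if (x_pc >= l)
    stop("`x_pc` must be < `l`: no rebinding region remains", call. = FALSE)
  if (x_pc < 0) stop("`x_pc` must be non-negative", call. = FALSE)
  if (is.null(u)) u <- runif(n)
  x_pc + (l - x_pc) * sqrt(u)
}

#' Mirror-reflect coordinates into an interval
#'
#' Reflective boundary conditions: interior points are unchanged, overshoots
#' are mirrored, and arbitrarily large overshoots fold repeatedly (closed
#' form via the triangle wave of period `2 (hi - lo)`).
#'
#' @param x Coordinate(s).
#' @param lo,hi Interval bounds.
#' @return Reflected coordinate(s) in `[lo, hi]`.
#' @examples
#' reflect_coord(c(-0.01, 0.1, 0.203), 0, 0.2)
#' @export
reflect_coord <- function(x, lo, hi) {
  stopifnot(hi > lo)
  w <- hi - lo
  z <- (x - lo) %% (2 * w)
  lo + pmin(z, 2 * w - z)
}

#' Reflect a 2-D position into the cell rectangle
#'
#' @param position Length-2 vector or two-column matrix (x, y), um.
#' @param l0,w0 Cell length and width, um; the rectangle is
#'   `[0, l0] x [-w0/2, w0/2]`.
#' @return Reflected position(s).
#' @export
reflect_into_cell <- function(position, l0, w0) {
  pos <- rbind(position)
  pos[, 1] <- reflect_coord(pos[, 1], 0, l0)
  pos[, 2] <- reflect_coord(pos[, 2], -w0 / 2, w0 / 2)
  if (is.null(dim(position))) drop(pos) else pos
}
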