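#' Initialise an explicit simulation state
#'
#' Builds the agent-level state used by the reference (pure R) stepping
#' functions: the partition complex at `(x0, y0)` and `n_ParA` DNA-bound
#' ParA-ATP dimers placed by [sample_rebinding_x()] with `x_pc = x0`
#' (uniform along the short axis), each tethered at its binding location.
#'
#' @param config A [sim_config()].
#' @return A list with elements `t`, `pc` (length-2 position), `dimers`
#'   (data frame with `x`, `y`, `eq_x`, `eq_y`, `state`, `next_event`) and
#'   `config`.
#' @export
init_sim_state <- function(config) {
  n <- config$n_ParA
  if (config$model == "diffusion") n <- 0L
  x <- sample_rebinding_x(n, config$x0, config$l0)
  y <- runif(n, -config$w0 / 2, config$w0 / 2)
  dimers <- data.frame(
    x = x, y = y, eq_x = x, eq_y = y,
    state = rep("dna_bound", n), next_event = rep(Inf, n),
    stringsAsFactors = FALSE)
  list(t = 0, pc = c(config$x0, config$y0), dimers = dimers, config = config)
}

#' Update ParA binding states
#'
#' Applies the stochastic state machine of the ParA cycle at the current
#' instant: (i) DNA-bound dimers whose disk overlaps the partition complex
#' (centre distance <= `R_PC + R_ParA`, boundary equality included) are
#' captured immediately and scheduled for release after an exponential dwell
#' of mean `1/k_cat`; (ii) captured dimers whose release time has passed
#' become free and are scheduled to rebind after an exponential wait of mean
#' `tau_db`; (iii) free dimers whose rebinding time has passed rebind at a
#' position drawn by [sample_rebinding_x()] (uniform short-axis), with a
#' fresh tether equilibrium point at that location. In the pure-diffusion
#' model this is a no-op.
#'
#' Waiting times are drawn once at state entry, which for exponential
#' distributions is statistically identical to per-step Bernoulli trials and
#' insensitive to time-step refinement.
#'
#' @param state A state list from [init_sim_state()].
#' @return The updated state.
#' @export
update_bindings <- function(state) {
  cfg <- state$config
  if (cfg$model == "diffusion" || nrow(state$dimers) == 0) return(state)
  d <- state$dimers
  if (any(d$state == "free" & is.finite(d$next_event) == FALSE))
    stop("internal consistency error: free dimer without a scheduled rebinding",
         call. = FALSE)
  t <- state$t

  rebind <- d$state == "free" & d$next_event <= t
  if (any(rebind)) {
    n <- sum(rebind)
    d$x[rebind] <- sample_rebinding_x(n, state$pc[1], cfg$l0)
    d$y[rebind] <- runif(n, -cfg$w0 / 2, cfg$w0 / 2)
    d$eq_x[rebind] <- d$x[rebind]
    d$eq_y[rebind] <- d$y[rebind]
    d$state[rebind] <- "dna_bound"
    d$next_event[rebind] <- Inf
  }

  release <- d$state == "pc_bound" & d$next_event <= t
  if (any(release)) {
    d$state[release] <- "free"
    d$next_event[release] <- t + rexp(sum(release), rate = 1 / cfg$tau_db)
  }

  dist2 <- (d$x - state$pc[1])^2 + (d$y - state$pc[2])^2
  capture <- d$state == "dna_bound" & dist2 <= (cfg$R_PC + cfg$R_ParA)^2
  if (any(capture)) {
    d$state[capture] <- "pc_bound"
    d$next_event[capture] <-
      if (cfg$k_cat > 0) t + rexp(sum(capture), rate = cfg$k_cat) else Inf
  }

  state$dimers <- d
  state
}

#' Advance the explicit state by one time step (reference implementation)
#'
#' Pure-R counterpart of the compiled engine, kept simple for cross-checks
#' on short runs: moves the complex (with tether forces in the DNA-relay
#' model; stalled while attached to an immobile dimer in the
#' diffusion-binding model), moves DNA-bound dimers in their harmonic wells,
#' lets captured dimers inherit the complex displacement exactly, applies
#' reflective boundaries and then [update_bindings()].
#'
#' @param state A state list from [init_sim_state()].
#' @return The advanced state (time incremented by `config$dt`).
#' @export
step_state <- function(state) {
  cfg <- state$config
  dt <- cfg$dt
  d <- state$dimers
  k_over_kT <- c(1 / cfg$sigma_long^2, 1 / cfg$sigma_short^2)
  relay <- cfg$model == "dna_relay"

  bound <- which(d$state == "pc_bound")
  pc_old <- state$pc
  pc_new <- pc_old
  stalled <- cfg$model == "diffusion_binding" && length(bound) > 0
  for (ax in if (stalled) integer(0) else 1:2) {
    f_over_kT <- 0
    fp_over_kT <- 0
    if (relay && length(bound) > 0) {
      pos <- if (ax == 1) d$x[bound] else d$y[bound]
      eq <- if (ax == 1) d$eq_x[bound] else d$eq_y[bound]
      f_over_kT <- sum((eq - pos) * k_over_kT[ax])
      fp_over_kT <- -length(bound) * k_over_kT[ax]
    }
    kt <- kT()
    pc_new[ax] <- bd_step(pc_old[ax], force = f_over_kT * kt,
                          force_deriv = fp_over_kT * kt,
                          D = cfg$D_PC, dt = dt)
  }
  pc_new <- reflect_into_cell(pc_new, cfg$l0, cfg$w0)
  shift <- pc_new - pc_old
  state$pc <- pc_new

  if (nrow(d) > 0 && relay) {
    d$x[bound] <- d$x[bound] + shift[1]
    d$y[bound] <- d$y[bound] + shift[2]
    dna <- which(d$state == "dna_bound")
    if (length(dna) > 0) {
      kt <- kT()
      fx <- spring_force(cbind(d$x[dna], d$y[dna]),
                         cbind(d$eq_x[dna], d$eq_y[dna]), k_over_kT)
      d$x[dna] <- bd_step(d$x[dna], fx$force[, 1], fx$deriv[1],
                          D = cfg$D_A, dt = dt)
      d$y[dna] <- bd_step(d$y[dna], fx$force[, 2], fx$deriv[2],
                          D = cfg$D_A, dt = dt)
      xy <- reflect_into_cell(cbind(d$x[dna], d$y[dna]), cfg$l0, cfg$w0)
      d$x[dna] <- xy[, 1]
      d$y[dna] <- xy[, 2]
    }
  }
  state$dimers <- d
  state$t <- state$t + dt
  update_bindings(state)
}
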