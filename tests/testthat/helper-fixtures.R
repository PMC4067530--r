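# Shared fixture helpers: tiny deterministic inputs built in code.

# Two spots on parallel lines separated along y; unambiguous linking.
parallel_two_spot_table <- function(n = 10, frame_s = 20, sep = 0.5) {
  x <- seq(0.5, 1.4, length.out = n)
  rbind(
    data.frame(frame = 1:n, t_s = (1:n - 1) * frame_s, x_um = x, y_um = 0),
    data.frame(frame = 1:n, t_s = (1:n - 1) * frame_s, x_um = x, y_um = sep))
}

# Piecewise trajectory: flat, linear rise, flat; with Gaussian noise.
piecewise_run_traj <- function(flat1_s = 300, run_s = 280, flat2_s = 300,
                               x_lo = 0.8, x_hi = 1.8, frame_s = 20,
                               noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  n1 <- round(flat1_s / frame_s)
  n2 <- round(run_s / frame_s)
  n3 <- round(flat2_s / frame_s)
  x <- c(rep(x_lo, n1), seq(x_lo, x_hi, length.out = n2 + 1)[-1],
         rep(x_hi, n3))
  n <- length(x)
  list(t_s = (seq_len(n) - 1) * frame_s,
       x_um = x + rnorm(n, 0, noise_sd),
       run_start = n1 + 1, run_end = n1 + n2)
}
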