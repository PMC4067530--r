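test_that("two parallel spots link with the identity assignment", {
  tab <- parallel_two_spot_table()
  linked <- link_two_spots(tab)
  t1 <- linked[linked$traj == 1, ]
  t2 <- linked[linked$traj == 2, ]
  expect_true(all(t1$y_um == 0))
  expect_true(all(t2$y_um == 0.5))
})

test_that("linking never swaps when swapping doubles total displacement", {
  # two near-crossing paths: straight-through assignment is cheaper at the
  # crossing frame; brute-force both assignments as oracle
  n <- 11
  xa <- seq(0, 1, length.out = n)
  xb <- seq(1, 0, length.out = n)
  tab <- rbind(
    data.frame(frame = 1:n, t_s = 1:n, x_um = xa, y_um = 0.02),
    data.frame(frame = 1:n, t_s = 1:n, x_um = xb, y_um = -0.02))
  linked <- link_two_spots(tab)
  for (k in 2:n) {
    prev <- linked[linked$frame == k - 1, ]
    cur <- linked[linked$frame == k, ]
    p <- function(df, tr) unlist(df[df$traj == tr, c("x_um", "y_um")])
    keep <- sum((p(cur, 1) - p(prev, 1))^2) + sum((p(cur, 2) - p(prev, 2))^2)
    swap <- sum((p(cur, 1) - p(prev, 2))^2) + sum((p(cur, 2) - p(prev, 1))^2)
    expect_lte(keep, swap)
  }
})

test_that("single-spot frames inherit the nearer previous label", {
  tab <- parallel_two_spot_table(n = 6)
  # frame 4 loses the y = 0.5 spot
  tab <- tab[!(tab$frame == 4 & tab$y_um == 0.5), ]
  linked <- link_two_spots(tab)
  expect_equal(linked$traj[linked$frame == 4], 1)
  # trajectory 2 resumes at frame 5 (gap bridged to last known position)
  expect_equal(sort(linked$frame[linked$traj == 2]), c(1:3, 5:6))
})

test_that("linking is permutation-invariant to spot order within a frame", {
  set.seed(14)
  tab <- parallel_two_spot_table(n = 8)
  shuffled <- do.call(rbind, lapply(split(tab, tab$frame), function(fr) {
    fr[sample(nrow(fr)), ]
  }))
  a <- link_two_spots(tab)
  b <- link_two_spots(shuffled)
  key <- function(df) df[order(df$traj, df$frame), c("traj", "x_um", "y_um")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  expect_error(link_two_spots(rbind(tab, tab[tab$frame == 2, ][1, ])),
               "more than 2")
})

test_that("fast-phase detection brackets a synthetic run within 2 frames", {
  pw <- piecewise_run_traj(seed = 2)
  ann <- detect_fast_phase(pw$t_s, pw$x_um)
  expect_true(ann$run_detected)
  expect_lte(abs(ann$run_start_idx - pw$run_start), 2)
  expect_lte(abs(ann$run_end_idx - pw$run_end), 2)
  m <- run_metrics(pw$t_s, pw$x_um, ann)
  expect_equal(m$run_length, 1.0, tolerance = 0.12)
  expect_equal(m$run_period, 280, tolerance = 0.3)
})

test_that("pure noise and zero-speed phases yield no run", {
  set.seed(15)
  t_s <- seq(0, 800, by = 20)
  flat <- 0.8 + rnorm(length(t_s), 0, 0.02)
  expect_false(detect_fast_phase(t_s, flat)$run_detected)
})

test_that("phase indices are invariant to time shifts and y reflection", {
  pw <- piecewise_run_traj(seed = 4)
  a <- detect_fast_phase(pw$t_s, pw$x_um)
  b <- detect_fast_phase(pw$t_s + 1234, pw$x_um)
  expect_equal(a[c("run_start_idx", "run_end_idx")],
               b[c("run_start_idx", "run_end_idx")])
})

test_that("run metrics compute speed as run length over period", {
  pw <- piecewise_run_traj(noise_sd = 0, seed = 1)
  ann <- detect_fast_phase(pw$t_s, pw$x_um)
  m <- run_metrics(pw$t_s, pw$x_um, ann)
  # 1.0 um over 280 s = 214 nm/min
  expect_equal(m$speed_nm_min, 1.0 / 280 * 6e4, tolerance = 0.12)
  expect_error(run_metrics(pw$t_s, pw$x_um, list(run_detected = FALSE)),
               "no run")
})

test_that("segment extraction implements the three printed rules", {
  frame_s <- 20
  # pre-duplication: single spot near pole then away from it
  n_pre <- 10
  pre <- data.frame(frame = 1:n_pre, t_s = (1:n_pre - 1) * frame_s,
                    x_um = c(rep(0.2, 4), rep(0.6, 6)), y_um = 0)
  # duplication at frame 11; separation visible immediately (>= 0.25 um)
  n_post <- 30
  fr <- n_pre + (1:n_post)
  prox <- data.frame(frame = fr, t_s = (fr - 1) * frame_s,
                     x_um = c(rep(0.5, 20), rep(0.25, 10)), y_um = 0)
  dist <- data.frame(frame = fr, t_s = (fr - 1) * frame_s,
                     x_um = 0.9 + 0.002 * (1:n_post), y_um = 0.1)
  linked <- link_two_spots(rbind(pre, prox, dist))
  segs <- extract_segments(linked, sep_um = 0.25)
  # segment 1: single-spot frames at >= 0.32 um from the pole -> frames 5-10
  expect_equal(sort(linked$frame[segs$segment1]), 5:10)
  # segment 2: proximal complex, from 60 s (3 frames) after separation
  # (frame 11) until it moves within 0.32 um of the pole (frame 31)
  s2_frames <- sort(linked$frame[segs$segment2])
  expect_equal(min(s2_frames), 14)
  expect_equal(max(s2_frames), 30)
  expect_true(all(linked$x_um[segs$segment2] >= 0.32))
  # segment 3: distal complex confined in a 0.5-um box from frame 14 on
  s3_frames <- sort(linked$frame[segs$segment3])
  expect_equal(min(s3_frames), 14)
  expect_equal(max(s3_frames), 40)
})

test_that("segment 3 picks the longest confined window before a run", {
  frame_s <- 20
  n_conf <- 36
  set.seed(16)
  conf <- 0.9 + runif(n_conf, -0.15, 0.15)  # confined within < 0.5 um
  run <- seq(1.1, 2.1, length.out = 10)     # then a 1-um excursion
  x_dist <- c(conf, run)
  n <- length(x_dist)
  dist <- data.frame(frame = 1:n, t_s = (1:n - 1) * frame_s, x_um = x_dist,
                     y_um = 0.1)
  prox <- data.frame(frame = 1:n, t_s = (1:n - 1) * frame_s, x_um = 0.4,
                     y_um = -0.1)
  linked <- link_two_spots(rbind(prox, dist))
  segs <- extract_segments(linked, sep_um = 0.25, settle_s = 60)
  s3 <- sort(linked$frame[segs$segment3])
  # brute-force oracle: longest window with x-range <= 0.5 among eligible rows
  eligible <- which(linked$traj == linked$traj[segs$segment3[1]] &
                      linked$t_s >= 60)
  x <- linked$x_um[eligible]
  best <- 0
  for (i in seq_along(x)) for (j in i:length(x)) {
    if (max(x[i:j]) - min(x[i:j]) <= 0.5) best <- max(best, j - i + 1)
  }
  expect_equal(length(s3), best)
  expect_lte(max(linked$x_um[segs$segment3]) -
               min(linked$x_um[segs$segment3]), 0.5)
})

test_that("Gaussian-displacement estimator recovers D within 10%", {
  g <- gen_free_diffusion(n_frames = 2001, D = 1e-4, frame_s = 20, seed = 3)
  est <- estimate_D_gaussian(diff(g$data$x_um), delta_t = 20)
  expect_equal(est$D, g$truth$D, tolerance = 0.10)
  # exact inversion: variance exactly 2 D dt
  d_exact <- c(rep(sqrt(2 * 1e-4 * 20), 50), rep(-sqrt(2 * 1e-4 * 20), 50))
  expect_equal(estimate_D_gaussian(d_exact, 20)$D, 1e-4)
  # doubling dt at fixed variance halves D
  expect_equal(estimate_D_gaussian(d_exact, 40)$D, 5e-5)
  expect_error(estimate_D_gaussian(rnorm(10), 20), "at least")
})

test_that("MSD estimator matches a brute-force MSD and recovers D", {
  set.seed(17)
  x50 <- cumsum(rnorm(50))
  m <- msd_1d(x50, max_lag = 10)
  brute <- sapply(1:10, function(k) {
    s <- 0
    cnt <- 0
    for (i in 1:(50 - k)) {
      s <- s + (x50[i + k] - x50[i])^2
      cnt <- cnt + 1
    }
    s / cnt
  })
  expect_equal(m$msd, brute)

  g <- gen_free_diffusion(n_frames = 1000, D = 1e-4, frame_s = 20, seed = 5)
  est <- estimate_D_msd(g$data$x_um, delta_t = 20)
  expect_equal(est$D, 1e-4, tolerance = 0.15)
  # static trajectory: D = 0
  est0 <- estimate_D_msd(rep(1.2, 100), delta_t = 20)
  expect_equal(est0$D, 0)
  # printed convention doubles the reported value
  est_p <- estimate_D_msd(g$data$x_um, delta_t = 20,
                          convention = "msd_equals_Dt")
  expect_equal(est_p$D, 2 * est$D)
})

test_that("both D estimators agree within 25% on long diffusive traces", {
  g <- gen_free_diffusion(n_frames = 4000, D = 1e-4, frame_s = 20, seed = 7)
  d1 <- estimate_D_gaussian(diff(g$data$x_um), 20)$D
  d2 <- estimate_D_msd(g$data$x_um, 20)$D
  expect_lt(abs(d1 - d2) / d1, 0.25)
})
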