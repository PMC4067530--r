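#' Link up-to-two spots per frame into two trajectories
#'
#' Greedy frame-to-frame assignment that minimises the total displacement of
#' the two spots relative to the last known position of each trajectory, the
#' rule used for two partition-complex spots tracked in the same cell. Frames
#' with a single localised spot assign it to the nearer trajectory; frames
#' with no spot leave a gap (bridged to the last known position for the next
#' assignment). Ties keep the previous labelling.
#'
#' @param spots Data frame with columns `frame`, `t_s`, `x_um`, `y_um`
#'   (one cell; at most two rows per frame).
#' @return Data frame with columns `frame`, `t_s`, `traj` (1 or 2), `x_um`,
#'   `y_um`. Trajectory 1 starts at the first spot observed in the first
#'   frame.
#' @export
link_two_spots <- function(spots) {
  stopifnot(all(c("frame", "t_s", "x_um", "y_um") %in% names(spots)))
  counts <- table(spots$frame)
  if (any(counts > 2))
    stop("malformed input: more than 2 spots in frame(s) ",
         paste(names(counts)[counts > 2], collapse = ", "), call. = FALSE)
  frames <- sort(unique(spots$frame))
  last <- matrix(NA_real_, 2, 2)  # last known (x, y) per trajectory
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- spots[spots$frame == frames[k], , drop = FALSE]
    pos <- cbind(fr$x_um, fr$y_um)
    if (nrow(fr) == 2) {
      if (anyNA(last)) {
        if (anyNA(last[1, ]) && anyNA(last[2, ])) {
          assign <- c(1L, 2L)  # first frame: keep input order
        } else {
          # one trajectory known: it takes the nearer spot
          known <- if (!anyNA(last[1, ])) 1L else 2L
          other <- 3L - known
          d1 <- sum((pos[1, ] - last[known, ])^2)
          d2 <- sum((pos[2, ] - last[known, ])^2)
          assign <- if (d1 <= d2) c(known, other) else c(other, known)
        }
      } else {
        keep <- sum((pos[1, ] - last[1, ])^2) + sum((pos[2, ] - last[2, ])^2)
        swap <- sum((pos[1, ] - last[2, ])^2) + sum((pos[2, ] - last[1, ])^2)
        assign <- if (swap < keep) c(2, 1) else c(1, 2)  # tie keeps labels
      }
      traj <- assign
    } else {  # single spot
      if (anyNA(last[1, ]) && anyNA(last[2, ])) {
        traj <- 1L
      } else if (anyNA(last[2, ])) {
        traj <- 1L
      } else if (anyNA(last[1, ])) {
        traj <- 2L
      } else {
        d1 <- sum((pos[1, ] - last[1, ])^2)
        d2 <- sum((pos[1, ] - last[2, ])^2)
        traj <- if (d2 < d1) 2L else 1L
      }
    }
    for (j in seq_len(nrow(fr))) last[traj[j], ] <- pos[j, ]
    out[[k]] <- data.frame(frame = fr$frame, t_s = fr$t_s, traj = traj,
                           x_um = fr$x_um, y_um = fr$y_um)
  }
  res <- do.call(rbind, out)
  res[order(res$traj, res$frame), , drop = FALSE]
}

#' Detect the fast (run) phase of a translocation trajectory
#'
#' Linearly interpolates the long-axis series onto its uniform frame grid,
#' smooths it with a moving average, and takes central-difference second
#' derivatives (themselves smoothed with the same window). Significant
#' curvature peaks (|d2| above `peak_k` robust SDs) mark candidate
#' inflection points; among opposite-sign peak pairs the one covering the
#' longest travelled distance defines the start and end of the run.
#'
#' @param t_s Time stamps, s.
#' @param x_um Long-axis positions, um (NA allowed; interpolated).
#' @param window Moving-average window, frames.
#' @param peak_k Curvature significance threshold in robust SDs.
#' @param min_run_length Minimum distance (um) between the inflection points
#'   for a run to be reported.
#' @param refine_halo Frames around the coarse inflection bracket searched
#'   when refining the changepoints by the profile likelihood of a
#'   three-segment Gaussian-increment model (zero-mean slow phase, drifting
#'   run, zero-mean anchored phase, free variance per segment); `0` disables
#'   refinement.
#' @return A list with `run_detected` (logical), `run_start_idx`,
#'   `run_end_idx` (frame indices on the uniform grid) and the smoothed
#'   series `x_smooth`.
#' @export
detect_fast_phase <- function(t_s, x_um, window = 5, peak_k = 3,
                              min_run_length = 0.3, refine_halo = 4) {
  stopifnot(length(t_s) == length(x_um), window >= 3)
  no_run <- list(run_detected = FALSE, run_start_idx = NA_integer_,
                 run_end_idx = NA_integer_, x_smooth = NULL)
  if (sum(!is.na(x_um)) < 2 * window) return(no_run)
  # uniform grid at the median frame interval, gaps interpolated
  dtf <- median(diff(t_s))
  grid <- seq(min(t_s), max(t_s), by = dtf)
  xi <- approx(t_s[!is.na(x_um)], x_um[!is.na(x_um)], xout = grid,
               rule = 2)$y
  ma <- function(v, w) {
    as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  }
  xs <- ma(xi, window)
  d2 <- c(NA, diff(xs, differences = 2), NA)
  d2 <- ma(d2, window)
  ok <- which(!is.na(d2))
  if (length(ok) < 4) return(no_run)
  # candidate inflection markers: clusters of significant curvature, with
  # the global curvature extremes always included (the acceleration into
  # and out of a genuine run dominates the second derivative)
  thr <- peak_k * mad(d2[ok], na.rm = TRUE)
  if (!is.finite(thr) || thr == 0) thr <- peak_k * sd(d2[ok])
  sig <- abs(d2) > thr & !is.na(d2)
  idx <- integer(0)
  if (any(sig)) {
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    idx <- vapply(which(runs$values), function(r) {
      span <- starts[r]:ends[r]
      span[which.max(abs(d2[span]))]
    }, integer(1))
  }
  idx <- unique(c(idx, ok[which.max(d2[ok])], ok[which.min(d2[ok])]))
  signs <- sign(d2[idx])
  if (length(idx) < 2) return(no_run)
  pairs <- expand.grid(a = seq_along(idx), b = seq_along(idx))
  pairs <- pairs[idx[pairs$a] < idx[pairs$b] &
                   signs[pairs$a] != signs[pairs$b], , drop = FALSE]
  if (nrow(pairs) == 0) return(no_run)
  pairs$dist <- abs(xs[idx[pairs$b]] - xs[idx[pairs$a]])
  pairs <- pairs[is.finite(pairs$dist) & pairs$dist > min_run_length, ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(no_run)
  # longest distance travelled; near-ties resolved by tightest bracketing
  dmax <- max(pairs$dist)
  near <- pairs[pairs$dist >= 0.97 * dmax, , drop = FALSE]
  best <- near[which.min(idx[near$b] - idx[near$a]), ]
  i <- idx[best$a]
  j <- idx[best$b]
  if (refine_halo > 0) {
    r <- .refine_changepoints(xi, i, j, refine_halo)
    i <- r[1]
    j <- r[2]
  }
  list(run_detected = TRUE, run_start_idx = i, run_end_idx = j,
       x_smooth = xs)
}

# Profile log-likelihood refinement of the run changepoints: increments are
# modelled as zero-mean Gaussian before the run, Gaussian with free mean
# during it, zero-mean after it, each with its own variance. Returns
# position indices (last pre-run point, last run point); falls back to the
# coarse bracket when the likelihood is degenerate (e.g. noiseless input).
.refine_changepoints <- function(x, i0, j0, halo) {
  inc <- diff(x)
  n <- length(inc)
  ll3 <- function(i, j) {
    s1 <- inc[seq_len(i)]
    s2 <- inc[(i + 1):j]
    s3 <- if (j < n) inc[(j + 1):n] else numeric(0)
    if (length(s1) < 2 || length(s2) < 2) return(-Inf)
    v1 <- mean(s1^2)
    v2 <- mean((s2 - mean(s2))^2)
    if (v1 <= 0 || v2 <= 0) return(-Inf)
    ll <- -length(s1) / 2 * log(v1) - length(s2) / 2 * log(v2)
    if (length(s3) >= 2) {
      v3 <- mean(s3^2)
      if (v3 <= 0) return(-Inf)
      ll <- ll - length(s3) / 2 * log(v3)
    }
    ll
  }
  best_ll <- -Inf
  bi <- max(1, min(i0, n - 1))
  bj <- max(bi + 1, min(j0, n))
  for (a in max(2, i0 - halo):min(n - 3, i0 + halo)) {
    for (b in max(a + 2, j0 - halo - 1):min(n - 1, j0 + halo - 1)) {
      ll <- ll3(a, b)
      if (ll > best_ll) {
        best_ll <- ll
        bi <- a
        bj <- b
      }
    }
  }
  if (!is.finite(best_ll)) return(c(i0, j0))
  c(bi, bj + 1)  # increment (bi, bj] -> positions bi .. bj+1
}

#' Run metrics of a detected fast phase
#'
#' @param t_s,x_um Trajectory (same grid passed to [detect_fast_phase()]).
#' @param annotation Result of [detect_fast_phase()].
#' @return A list (`phase_annotation`) with `x_start`, `x_finish`,
#'   `run_length` (um), `run_period` (s), `speed_um_s` and `speed_nm_min`.
#' @export
run_metrics <- function(t_s, x_um, annotation) {
  if (!isTRUE(annotation$run_detected))
    stop("no run detected; metrics undefined", call. = FALSE)
  i <- annotation$run_start_idx
  j <- annotation$run_end_idx
  stopifnot(i < j)
  x_start <- x_um[i]
  x_finish <- x_um[j]
  run_length <- abs(x_finish - x_start)
  run_period <- t_s[j] - t_s[i]
  list(run_start_idx = i, run_end_idx = j,
       x_start = x_start, x_finish = x_finish,
       run_length = run_length, run_period = run_period,
       speed_um_s = run_length / run_period,
       speed_nm_min = run_length / run_period * 1000 * 60)
}

#' Extract the three diffusive trajectory segments
#'
#' Implements the segment definitions used to estimate the partition-complex
#' diffusion coefficient outside the directed phase:
#' * segment 1: frames before duplication (a single spot in the cell) with
#'   the complex at least `pole_margin` from the old pole;
#' * segment 2 (old-pole-proximal complex): from `settle_s` after the two
#'   complexes become visibly separated until the complex moves within
#'   `pole_margin` of the old pole;
#' * segment 3 (distal complex): the longest stretch, starting `settle_s`
#'   after separation, confined within a `box_um`-wide window along the long
#'   axis.
#'
#' @param linked Output of [link_two_spots()] (columns `frame`, `t_s`,
#'   `traj`, `x_um`, `y_um`).
#' @param pole_margin Distance from the old pole (x = 0), um; default 0.32.
#' @param settle_s Delay after visible separation, s; default 60.
#' @param box_um Confinement box width, um; default 0.5.
#' @param sep_um Separation needed for two spots to count as "visibly
#'   separated", um; default 0.25 (about twice the localization SD).
#' @return A list of integer row-index vectors (`segment1`, `segment2`,
#'   `segment3`) into `linked`; empty when no frames qualify.
#' @export
extract_segments <- function(linked, pole_margin = 0.32, settle_s = 60,
                             box_um = 0.5, sep_um = 0.25) {
  frames <- sort(unique(linked$frame))
  per_frame <- split(seq_len(nrow(linked)), linked$frame)
  n_spots <- vapply(per_frame, length, integer(1))

  sep_frame <- NA_real_
  for (k in seq_along(frames)) {
    rows <- per_frame[[k]]
    if (length(rows) == 2) {
      d <- sqrt(diff(linked$x_um[rows])^2 + diff(linked$y_um[rows])^2)
      if (d >= sep_um) {
        sep_frame <- frames[k]
        break
      }
    }
  }

  # segment 1: single-spot frames before separation, away from the old pole
  pre <- if (is.na(sep_frame)) frames else frames[frames < sep_frame]
  seg1 <- integer(0)
  for (k in which(frames %in% pre)) {
    rows <- per_frame[[k]]
    if (length(rows) == 1 && linked$x_um[rows] >= pole_margin)
      seg1 <- c(seg1, rows)
  }

  seg2 <- integer(0)
  seg3 <- integer(0)
  if (!is.na(sep_frame)) {
    t_sep <- linked$t_s[match(sep_frame, linked$frame)]
    after <- linked$t_s >= t_sep + settle_s
    # proximal / distal assignment from mean long-axis position
    mean_x <- tapply(linked$x_um, linked$traj, mean)
    prox <- as.integer(names(which.min(mean_x)))
    dist <- as.integer(names(which.max(mean_x)))

    rows2 <- which(linked$traj == prox & after)
    rows2 <- rows2[order(linked$frame[rows2])]
    if (length(rows2) > 0) {
      hit <- which(linked$x_um[rows2] < pole_margin)
      if (length(hit) > 0) rows2 <- rows2[seq_len(hit[1] - 1)]
      seg2 <- rows2
    }

    rows3 <- which(linked$traj == dist & after)
    rows3 <- rows3[order(linked$frame[rows3])]
    if (length(rows3) >= 2) {
      x <- linked$x_um[rows3]
      best_len <- 0
      lo <- 1
      best <- integer(0)
      for (hi in seq_along(x)) {  # two-pointer longest window with range <= box
        while (max(x[lo:hi]) - min(x[lo:hi]) > box_um) lo <- lo + 1
        if (hi - lo + 1 > best_len) {
          best_len <- hi - lo + 1
          best <- lo:hi
        }
      }
      seg3 <- rows3[best]
    }
  }
  list(segment1 = seg1, segment2 = seg2, segment3 = seg3)
}

#' Diffusion coefficient from a Gaussian fit to displacements
#'
#' Fits a zero-mean Gaussian to one-dimensional displacements at lag
#' `delta_t` and converts the fitted variance to a diffusion coefficient.
#' The physics convention `Var = 2 D delta_t` for 1-D displacements is the
#' default; `convention = "msd_equals_Dt"` uses `Var = D delta_t` instead
#' (the convention in which an MSD slope is quoted directly as D).
#'
#' @param displacements 1-D displacements, um.
#' @param delta_t Lag, s.
#' @param convention `"var_2Ddt"` (default) or `"msd_equals_Dt"`.
#' @param min_n Minimum number of displacements (default 50).
#' @return A list (`diffusion_estimate`) with `D` (um^2/s), `D_se`,
#'   `sigma` (fitted SD, um), `method`, `n`.
#' @export
estimate_D_gaussian <- function(displacements, delta_t,
                                convention = c("var_2Ddt", "msd_equals_Dt"),
                                min_n = 50) {
  convention <- match.arg(convention)
  displacements <- displacements[!is.na(displacements)]
  n <- length(displacements)
  if (n < min_n)
    stop("need at least ", min_n, " displacements", call. = FALSE)
  v <- mean(displacements^2)  # ML variance of a zero-mean Gaussian
  if (v == 0)
    return(list(D = NA_real_, D_se = NA_real_, sigma = 0,
                method = "gaussian_displacement", n = n, failed = TRUE))
  denom <- if (convention == "var_2Ddt") 2 * delta_t else delta_t
  v_se <- v * sqrt(2 / n)  # SE of the variance of a Gaussian sample
  list(D = v / denom, D_se = v_se / denom, sigma = sqrt(v),
       method = "gaussian_displacement", n = n, failed = FALSE,
       convention = convention)
}

#' Time-averaged mean squared displacement
#'
#' @param x Positions on a uniform time grid, um (1-D).
#' @param max_lag Largest lag (frames).
#' @return Data frame with `lag` (frames) and `msd` (um^2), averaging over
#'   all start points per lag.
#' @export
msd_1d <- function(x, max_lag = min(length(x) - 1, 20)) {
  stopifnot(max_lag >= 1, length(x) > max_lag)
  msd <- vapply(seq_len(max_lag), function(k) {
    d <- x[(1 + k):length(x)] - x[seq_len(length(x) - k)]
    mean(d^2, na.rm = TRUE)
  }, numeric(1))
  data.frame(lag = seq_len(max_lag), msd = msd)
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Ordinary least squares on the first `n_points` MSD lags with a free
#' offset (`MSD = slope * t + C`; the offset absorbs localization noise).
#' Under the standard 1-D convention the slope equals `2 D`; the
#' `"msd_equals_Dt"` convention reports the slope itself as D.
#'
#' @param x Positions on a uniform grid, um.
#' @param delta_t Frame interval, s.
#' @param n_points Number of MSD lags fitted (default 4).
#' @param convention `"var_2Ddt"` (default, slope = 2D) or
#'   `"msd_equals_Dt"` (slope = D).
#' @return A list (`diffusion_estimate`) with `D`, `D_se`, `offset`,
#'   `method`, `n`.
#' @export
estimate_D_msd <- function(x, delta_t,
                           convention = c("var_2Ddt", "msd_equals_Dt"),
                           n_points = 4) {
  convention <- match.arg(convention)
  x <- x[!is.na(x)]
  if (length(x) <= n_points)
    stop("trajectory too short for ", n_points, " MSD lags", call. = FALSE)
  m <- msd_1d(x, max_lag = n_points)
  fit <- lm(msd ~ I(lag * delta_t), data = m)
  slope <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  denom <- if (convention == "var_2Ddt") 2 else 1
  list(D = slope / denom, D_se = se / denom,
       offset = unname(coef(fit)[1]), method = "msd_linear",
       n = length(x), convention = convention)
}
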