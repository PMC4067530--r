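#' Convert per-cell molecule counts to concentrations
#'
#' `concentration = N / (N_A V)`: molecules divided by the Avogadro constant
#' and the compartment volume. Moles can be supplied directly in place of a
#' molecule count.
#'
#' @param molecules Molecules per cell (ignored if `moles` given).
#' @param volume_fL Compartment volume, fL.
#' @param moles Optional amount in mol (overrides `molecules`).
#' @return Concentration, uM.
#' @examples
#' molecules_to_concentration(moles = 0.2e-21, volume_fL = 0.25)  # 0.8 uM
#' molecules_to_concentration(180, 0.25)
#' @export
molecules_to_concentration <- function(molecules = NULL, volume_fL,
                                       moles = NULL) {
  if (volume_fL <= 0) stop("`volume_fL` must be positive", call. = FALSE)
  if (is.null(moles)) {
    if (is.null(molecules) || any(molecules < 0))
      stop("`molecules` must be a non-negative count", call. = FALSE)
    moles <- molecules / 6.022e23
  }
  moles / (volume_fL * 1e-15) * 1e6  # mol / L -> uM
}

#' In-vivo DNA concentration from chromosome size
#'
#' Chromosome mass (`bp * mass_per_bp`, Da converted to grams) divided by the
#' cell volume.
#'
#' @param bp Base pairs per chromosome.
#' @param mass_per_bp_Da Average mass per base pair, Da (default 650).
#' @param volume_ml Cell volume, ml.
#' @return Concentration, mg/ml.
#' @examples
#' dna_concentration(4e6, 650, 2.5e-13)  # ~17 mg/ml
#' @export
dna_concentration <- function(bp, mass_per_bp_Da = 650, volume_ml) {
  stopifnot(bp >= 0, mass_per_bp_Da > 0, volume_ml > 0)
  grams <- bp * mass_per_bp_Da / 6.022e23
  grams / volume_ml * 1000  # g/ml -> mg/ml
}

#' Fraction of fluorescence in the partition complex
#'
#' Ranks cell segments by fluorescence density (fluorescence / area), takes
#' the lowest decile (`ceiling(0.1 n)` segments, ties broken by segment
#' index) as representative of freely diffusing signal, scales its mean
#' density to the whole cell area, and reports
#' `1 - diffuse signal / total signal`.
#'
#' @param fluorescence Per-segment fluorescence totals.
#' @param area Per-segment areas (same length).
#' @param decile Fraction of segments treated as background (default 0.1).
#' @return Fraction of signal in the focus, in `[0, 1]`.
#' @examples
#' partition_fraction(c(8, rep(2 / 9, 9)), rep(1, 10))
#' @export
partition_fraction <- function(fluorescence, area, decile = 0.1) {
  stopifnot(length(fluorescence) == length(area), all(area > 0))
  n <- length(fluorescence)
  if (n < 10) stop("need at least 10 segments", call. = FALSE)
  total <- sum(fluorescence)
  if (total <= 0) stop("zero total fluorescence: fraction undefined",
                       call. = FALSE)
  dens <- fluorescence / area
  k <- ceiling(decile * n)
  low <- order(dens, seq_len(n))[seq_len(k)]  # ties broken by segment index
  diffuse <- mean(dens[low]) * sum(area)
  max(0, min(1, 1 - diffuse / total))
}

#' Fit a two-component Gaussian mixture
#'
#' Maximum-likelihood fit of a bimodal Gaussian (unequal variances) used to
#' split a fluorescence histogram into autofluorescent and expressing
#' populations. Components are ordered by ascending mean; the lower-mean
#' component is the autofluorescence reference.
#'
#' @param values Numeric vector (>= 100 values).
#' @param min_separation Components closer than this many pooled SDs are
#'   flagged as collapsed (default 2: a Gaussian mixture needs more than
#'   about two SDs of separation to be bimodal at all).
#' @return A list (`bimodal_fit`) with `means`, `sds`, `weights` (ascending
#'   mean order), `af_mean` (lower mean), `collapsed` (logical),
#'   `converged`.
#' @export
fit_bimodal_gaussian <- function(values, min_separation = 2) {
  values <- values[is.finite(values)]
  if (length(values) < 100) stop("need at least 100 values", call. = FALSE)
  # Mclust evaluates `mclustBIC` in the caller's frame; bind it locally so
  # the namespace need not be attached
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    mclust::Mclust(values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(means = c(NA, NA), sds = c(NA, NA), weights = c(NA, NA),
                af_mean = NA_real_, collapsed = NA, converged = FALSE))
  ord <- order(fit$parameters$mean)
  means <- fit$parameters$mean[ord]
  sds <- sqrt(fit$parameters$variance$sigmasq)[ord]
  weights <- fit$parameters$pro[ord]
  sep <- diff(means) / mean(sds)
  list(means = unname(means), sds = unname(sds), weights = unname(weights),
       af_mean = unname(means[1]),
       collapsed = !is.finite(sep) || sep < min_separation,
       converged = TRUE)
}

#' Aspect ratio of a fluorescent object from its point set
#'
#' Major and minor axis lengths of the ellipse with the same second central
#' moments as the (optionally weighted) point cloud, using the
#' `4 * sqrt(eigenvalue)` axis-length convention; the aspect ratio is their
#' quotient and objects with `AR > cutoff` are scored as decompacted
#' (stretched).
#'
#' @param points Two-column matrix or data frame of (x, y) coordinates.
#' @param weights Optional non-negative weights (e.g. pixel intensities).
#' @param cutoff Decompaction cutoff on the aspect ratio (default 1.5).
#' @return A list (`ar_record`) with `aspect_ratio`, `major`, `minor`
#'   (lengths in input units), `angle_rad`, `decompacted`, `degenerate`.
#' @examples
#' set.seed(1)
#' pts <- cbind(rnorm(500, sd = 3), rnorm(500, sd = 1))
#' aspect_ratio(pts)$aspect_ratio  # ~3
#' @export
aspect_ratio <- function(points, weights = NULL, cutoff = 1.5) {
  m <- as.matrix(points)
  stopifnot(ncol(m) == 2)
  if (nrow(m) < 3)
    stop("need at least 3 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  ctr <- colSums(m * w)
  d <- sweep(m, 2, ctr)
  cov2 <- crossprod(d * sqrt(w))
  ev <- eigen(cov2, symmetric = TRUE)
  if (ev$values[2] <= .Machine$double.eps * ev$values[1] ||
      ev$values[1] <= 0)
    return(list(aspect_ratio = NA_real_, major = NA_real_, minor = NA_real_,
                angle_rad = NA_real_, decompacted = NA, degenerate = TRUE))
  major <- 4 * sqrt(ev$values[1])
  minor <- 4 * sqrt(ev$values[2])
  ar <- major / minor
  list(aspect_ratio = ar, major = major, minor = minor,
       angle_rad = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       decompacted = ar > cutoff, degenerate = FALSE)
}

#' Bin decompaction calls by relative cell position
#'
#' Summarises per-object aspect-ratio calls along the normalised cell
#' coordinate (old pole = 0, new pole = 1).
#'
#' @param rel_position Relative positions in `[0, 1]`.
#' @param aspect_ratios Matching aspect ratios.
#' @param breaks Bin edges on `[0, 1]`.
#' @param cutoff Decompaction cutoff (default 1.5).
#' @return Data frame with `bin_mid`, `n` and `frac_decompacted`.
#' @export
decompaction_profile <- function(rel_position, aspect_ratios,
                                 breaks = seq(0, 1, by = 0.1),
                                 cutoff = 1.5) {
  stopifnot(length(rel_position) == length(aspect_ratios))
  bin <- cut(rel_position, breaks, include.lowest = TRUE)
  agg <- tapply(aspect_ratios > cutoff, bin, function(z) mean(z, na.rm = TRUE))
  n <- tapply(aspect_ratios, bin, length)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  data.frame(bin_mid = mids, n = as.integer(ifelse(is.na(n), 0, n)),
             frac_decompacted = as.numeric(agg))
}
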