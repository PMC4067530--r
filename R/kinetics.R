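#' Initial velocity of an NADH-coupled ATPase time course
#'
#' Ordinary least-squares slope of A340 against time over the initial window,
#' optionally corrected by subtracting the slope of a matched no-enzyme
#' control (spontaneous ATP hydrolysis and NADH oxidation). A340 declines as
#' ADP is produced, so active wells have negative slopes.
#'
#' @param t_min Time points, min.
#' @param a340 Absorbance at 340 nm.
#' @param window Length-2 time window (min) over which to fit; default the
#'   whole course.
#' @param control_slope Slope of the matched control (absorbance/min) to
#'   subtract; default 0.
#' @param drift_tol Positive-drift tolerance (absorbance/min); a fitted slope
#'   above it flags a gross artifact.
#' @return A list with `slope` (absorbance/min, control-corrected),
#'   `slope_se`, `n` and `flagged`.
#' @export
initial_velocity <- function(t_min, a340, window = range(t_min),
                             control_slope = 0, drift_tol = 1e-3) {
  keep <- t_min >= window[1] & t_min <= window[2] & !is.na(a340)
  if (sum(keep) < 4)
    stop("need at least 4 points in the fitting window", call. = FALSE)
  fit <- lm(a340[keep] ~ t_min[keep])
  slope <- unname(coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])  # exact fits warn
  list(slope = slope - control_slope, slope_se = se,
       n = sum(keep), flagged = slope > drift_tol)
}

#' Convert an absorbance slope to an ADP production rate
#'
#' One ADP oxidises one NADH in the coupled assay, so the A340 decline rate
#' times the NADH standard-curve factor gives the ADP production rate.
#'
#' @param slope A340 slope, absorbance/min (negative for active wells).
#' @param nadh_standard Standard-curve factor, uM NADH per absorbance unit.
#' @return ADP production rate, uM/hr (positive for active wells).
#' @examples
#' convert_to_rate(-0.002, nadh_standard = 500)
#' @export
convert_to_rate <- function(slope, nadh_standard) {
  stopifnot(nadh_standard > 0)
  -slope * nadh_standard * 60
}

#' Specific ATPase activity
#'
#' ADP production rate divided by the enzyme concentration. Rates below the
#' assay baseline are reported as censored ("< baseline").
#'
#' @param rate_uM_hr ADP production rate, uM/hr.
#' @param parA_uM ParA concentration, uM (> 0).
#' @param baseline_hr Assay detection baseline, /hr (default 0.5).
#' @return A list with `activity_hr` (/hr), `below_baseline` (logical) and
#'   `label` (e.g. `"<0.5 hr-1"` when censored).
#' @export
specific_activity <- function(rate_uM_hr, parA_uM, baseline_hr = 0.5) {
  if (parA_uM <= 0)
    stop("specific activity undefined for [ParA] <= 0", call. = FALSE)
  act <- rate_uM_hr / parA_uM
  below <- act < baseline_hr
  list(activity_hr = act, below_baseline = below,
       label = if (below) paste0("<", baseline_hr, " hr-1")
               else sprintf("%.3g hr-1", act))
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of `v = Vmax S / (K + S)`, initialised at
#' `Vmax0 = max(v)`, `K0 = median(S)`; with rates expressed as specific
#' activities (per uM enzyme), the fitted Vmax is directly k_cat in /hr.
#' Falls back to Levenberg-Marquardt (`minpack.lm`) if the default
#' Gauss-Newton fit does not converge.
#'
#' @param S Substrate concentrations (any units; K is reported in them).
#' @param v Rates (specific activities), /hr.
#' @return A list (`mm_fit`) with `vmax`, `K`, `vmax_se`, `K_se`,
#'   `converged`, `fit` (the nls object).
#' @examples
#' S <- c(10, 20, 40, 80, 160, 320)
#' fit_michaelis_menten(S, 120 * S / (80 + S))
#' @export
fit_michaelis_menten <- function(S, v) {
  stopifnot(length(S) == length(v), all(v >= 0))
  if (length(unique(S)) < 4)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  df <- data.frame(S = S, v = v)
  start <- list(vmax = max(v), K = median(S))
  fit <- tryCatch(
    nls(v ~ vmax * S / (K + S), data = df, start = start),
    error = function(e) tryCatch(
      minpack.lm::nlsLM(v ~ vmax * S / (K + S), data = df, start = start),
      error = function(e2) NULL))
  if (is.null(fit))
    return(list(vmax = NA_real_, K = NA_real_, vmax_se = NA_real_,
                K_se = NA_real_, converged = FALSE, fit = NULL))
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, 2]
  list(vmax = unname(cf["vmax"]), K = unname(cf["K"]),
       vmax_se = unname(se["vmax"]), K_se = unname(se["K"]),
       converged = TRUE, fit = fit)
}

#' Linear (first-order) rate fit against enzyme concentration
#'
#' When DNA is near-saturating, the ADP production rate is proportional to
#' the ParA concentration; the through-origin slope is k_cat in /hr.
#'
#' @param parA_uM ParA concentrations, uM.
#' @param rate_uM_hr ADP production rates, uM/hr.
#' @param through_origin Fit `rate = k_cat [ParA]` (default) or allow a free
#'   intercept.
#' @return A list with `k_cat_hr`, `k_cat_se`, `intercept` (0 when through
#'   the origin) and `fit`.
#' @export
fit_linear_rate <- function(parA_uM, rate_uM_hr, through_origin = TRUE) {
  stopifnot(length(parA_uM) == length(rate_uM_hr))
  if (length(parA_uM) < 3) stop("need at least 3 points", call. = FALSE)
  fit <- if (through_origin) lm(rate_uM_hr ~ 0 + parA_uM)
         else lm(rate_uM_hr ~ parA_uM)
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(k_cat_hr = unname(coef(fit)[["parA_uM"]]),
       k_cat_se = cf["parA_uM", 2],
       intercept = if (through_origin) 0 else unname(coef(fit)[1]),
       fit = fit)
}

#' Convert a catalytic rate between per-hour and per-second
#'
#' @param k Rate value.
#' @param from Units of `k`: `"hr"` or `"s"`.
#' @return The rate in the other unit.
#' @examples
#' convert_rate_units(120, "hr")  # 0.0333 /s
#' @export
convert_rate_units <- function(k, from = c("hr", "s")) {
  from <- match.arg(from)
  if (from == "hr") k / 3600 else k * 3600
}
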