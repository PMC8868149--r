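## Segment interpolant used by the AUC rule: linear on rising or flat
## segments and on any segment touching zero; exponential on strictly
## declining positive segments (for which the log-trapezoid is exact).
.seg_interp <- function(t1, t2, c1, c2, t) {
  if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
    c1 + (c2 - c1) * (t - t1) / (t2 - t1)
  } else {
    c1 * (c2 / c1)^((t - t1) / (t2 - t1))
  }
}

.seg_auc <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
    (c1 + c2) * dt / 2
  } else {
    (c1 - c2) * dt / log(c1 / c2)
  }
}

.check_window <- function(profile, t0, t1) {
  if (nrow(profile) < 2) stop("profile needs at least 2 points", call. = FALSE)
  if (t1 <= t0) stop("window end must exceed window start", call. = FALSE)
  if (t0 < profile$time[1] || t1 > profile$time[nrow(profile)]) {
    stop(sprintf("window [%g, %g] outside profile span [%g, %g]",
                 t0, t1, profile$time[1], profile$time[nrow(profile)]),
         call. = FALSE)
  }
}

#' Interpolate a profile at arbitrary times with the AUC segment rule
#'
#' Rising (and flat, and zero-touching) segments are interpolated linearly;
#' strictly declining positive segments exponentially, matching the
#' linear-up/log-down AUC rule.
#'
#' @param profile a [conc_profile()].
#' @param t times within the profile span.
#' @return Interpolated concentrations.
#' @export
interp_conc <- function(profile, t) {
  tt <- profile$time; cc <- profile$conc
  if (any(t < tt[1] | t > tt[length(tt)])) {
    stop("interpolation time outside profile span", call. = FALSE)
  }
  vapply(t, function(ti) {
    i <- findInterval(ti, tt, rightmost.closed = TRUE)
    if (ti == tt[i]) return(cc[i])
    .seg_interp(tt[i], tt[i + 1], cc[i], cc[i + 1], ti)
  }, numeric(1))
}

#' Area under the curve by the linear-up/log-down trapezoidal method
#'
#' Rising or flat segments (and segments touching zero concentration)
#' contribute linear trapezoids `(C_i + C_(i+1)) * dt / 2`; strictly
#' declining positive segments contribute logarithmic trapezoids
#' `(C_i - C_(i+1)) * dt / log(C_i / C_(i+1))`, which integrate an
#' exponential decline exactly. Window endpoints falling inside a segment
#' are evaluated with the matching segment interpolant, which makes the
#' rule additive over adjacent windows.
#'
#' @param profile a [conc_profile()] covering `[t0, t1]`.
#' @param t0,t1 integration window, minutes.
#' @return AUC in min*ug/mL.
#' @examples
#' p <- conc_profile(c(0, 10), c(0, 10))
#' auc_lin_up_log_down(p, 0, 10)  # 50
#' @export
auc_lin_up_log_down <- function(profile, t0, t1) {
  .check_window(profile, t0, t1)
  tt <- profile$time; cc <- profile$conc
  inner <- tt > t0 & tt < t1
  kt <- c(t0, tt[inner], t1)
  kc <- c(interp_conc(profile, t0), cc[inner], interp_conc(profile, t1))
  total <- 0
  for (i in seq_len(length(kt) - 1)) {
    total <- total + .seg_auc(kt[i], kt[i + 1], kc[i], kc[i + 1])
  }
  total
}

#' Peak concentration and its time within a dosing interval
#'
#' `cmax` is the maximum of the recorded concentrations inside the window;
#' `tmax` is the earliest time attaining it, reported relative to the
#' interval's dose start.
#'
#' @param profile a [conc_profile()].
#' @param window `c(start, end)` absolute minutes; points with
#'   `start <= time < end` are considered.
#' @param dose_start absolute time of the interval's dose (defaults to the
#'   window start).
#' @return list with `cmax` (ug/mL) and `tmax` (min from `dose_start`).
#' @export
cmax_tmax <- function(profile, window, dose_start = window[1]) {
  sel <- profile$time >= window[1] & profile$time < window[2]
  if (!any(sel)) stop("no points in the interval", call. = FALSE)
  tt <- profile$time[sel]; cc <- profile$conc[sel]
  i <- which.max(cc)  # ties resolve to the earliest time (sorted input)
  list(cmax = cc[i], tmax = tt[i] - dose_start)
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Ordinary least-squares fit of `log(conc)` on time over all points strictly
#' after the interval's Tmax, within the window, with positive concentration
#' and not flagged BLQ. The fit requires at least `min_points` points;
#' a non-negative slope yields an undefined rate rather than an error.
#'
#' @param profile a [conc_profile()].
#' @param window `c(start, end)` absolute minutes.
#' @param min_points minimum number of eligible points (default 3).
#' @return list: `lambda_eq` (1/min or `NA`), `n_lambda_points`, `reason`
#'   (`NA` when defined, else `"insufficient points"` or
#'   `"non-negative slope"`).
#' @export
terminal_lambda <- function(profile, window, min_points = 3) {
  sel <- profile$time >= window[1] & profile$time < window[2]
  tt <- profile$time[sel]; cc <- profile$conc[sel]
  blq <- profile$blq[sel]
  if (!length(tt)) {
    return(list(lambda_eq = NA_real_, n_lambda_points = 0L,
                reason = "insufficient points"))
  }
  tmax_abs <- tt[which.max(cc)]
  use <- tt > tmax_abs & cc > 0 & !blq
  n <- sum(use)
  if (n < min_points) {
    return(list(lambda_eq = NA_real_, n_lambda_points = as.integer(n),
                reason = "insufficient points"))
  }
  x <- tt[use]; y <- log(cc[use])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  if (slope >= 0) {
    return(list(lambda_eq = NA_real_, n_lambda_points = as.integer(n),
                reason = "non-negative slope"))
  }
  list(lambda_eq = -slope, n_lambda_points = as.integer(n), reason = NA_character_)
}

#' Terminal half-life from the elimination rate constant
#'
#' @param lambda_eq terminal elimination rate, 1/min.
#' @return `log(2) / lambda_eq` in minutes; `NA` when the rate is undefined
#'   or non-positive.
#' @examples
#' half_life(log(2) / 46)  # 46
#' @export
half_life <- function(lambda_eq) {
  ifelse(is.na(lambda_eq) | lambda_eq <= 0, NA_real_, log(2) / lambda_eq)
}

#' Tissue penetration ratio
#'
#' The standard tissue-exposure index `AUC_tissue / AUC_plasma` over matched
#' windows.
#'
#' @param auc_tissue,auc_plasma AUCs in min*ug/mL; `auc_plasma` must be
#'   positive.
#' @return Dimensionless ratio.
#' @examples
#' penetration_ratio(4147, 2521)  # 1.645
#' @export
penetration_ratio <- function(auc_tissue, auc_plasma) {
  if (any(auc_plasma <= 0)) stop("plasma AUC must be positive", call. = FALSE)
  auc_tissue / auc_plasma
}

## BLQ rule for AUC: flagged values after the last quantifiable point are set
## to zero; earlier flagged values are treated as missing (dropped).
.auc_ready_profile <- function(profile) {
  if (!any(profile$blq)) return(profile)
  last_q <- max(c(-Inf, profile$time[!profile$blq]))
  keep <- !profile$blq | profile$time > last_q
  conc <- ifelse(profile$blq & profile$time > last_q, 0, profile$conc)
  conc_profile(profile$time[keep], conc[keep], FALSE,
               subject_id = attr(profile, "subject_id"),
               compartment = attr(profile, "compartment"))
}

#' Non-compartmental metrics for one profile and dosing interval
#'
#' @param profile a full-study [conc_profile()] (absolute clock).
#' @param window analysis window `c(start, end)`, absolute minutes.
#' @param dose_start absolute dose time for the interval.
#' @param interval_index reported interval number.
#' @param min_lambda_points minimum points for the terminal fit.
#' @return One-row tibble: `interval_index`, `auc`, `cmax`, `tmax`,
#'   `lambda_eq`, `t_half`, `n_lambda_points`, `lambda_reason`.
#' @export
nca_interval <- function(profile, window, dose_start = window[1],
                         interval_index = 1L, min_lambda_points = 3) {
  quant <- profile[!profile$blq, , drop = FALSE]
  pk <- cmax_tmax(quant, window, dose_start)
  lam <- terminal_lambda(profile, window, min_points = min_lambda_points)
  auc <- auc_lin_up_log_down(.auc_ready_profile(profile), window[1], window[2])
  tibble::tibble(interval_index = as.integer(interval_index), auc = auc,
                 cmax = pk$cmax, tmax = pk$tmax, lambda_eq = lam$lambda_eq,
                 t_half = half_life(lam$lambda_eq),
                 n_lambda_points = lam$n_lambda_points,
                 lambda_reason = lam$reason)
}

#' Non-compartmental analysis of a whole cohort
#'
#' Computes per subject x compartment x dosing interval AUC (linear-up/
#' log-down), Cmax, Tmax, terminal rate and half-life, plus the tissue
#' penetration ratio against the same subject and interval's plasma AUC.
#'
#' @param profiles tibble from [build_cohort_profiles()].
#' @param dose_times dose start times, minutes.
#' @param windows tibble from [analysis_windows()] (defaults to the standard
#'   450-min observation span after each dose).
#' @param min_lambda_points minimum points for the terminal fit.
#' @return tibble with one row per subject x compartment x interval.
#' @export
run_nca <- function(profiles, dose_times = c(0, 480),
                    windows = analysis_windows(dose_times),
                    min_lambda_points = 3) {
  combos <- unique(profiles[c("subject_id", "compartment")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    pr <- profile_of(profiles, combos$subject_id[i], combos$compartment[i])
    for (k in seq_len(nrow(windows))) {
      row <- nca_interval(pr, c(windows$win_start[k], windows$win_end[k]),
                          dose_start = windows$dose_start[k],
                          interval_index = windows$interval_index[k],
                          min_lambda_points = min_lambda_points)
      out[[length(out) + 1]] <- tibble::tibble(
        subject_id = combos$subject_id[i],
        compartment = combos$compartment[i], row)
    }
  }
  res <- dplyr::bind_rows(out)
  plasma <- res[res$compartment == "plasma",
                c("subject_id", "interval_index", "auc")]
  names(plasma)[3] <- "auc_plasma"
  res <- dplyr::left_join(res, plasma, by = c("subject_id", "interval_index"))
  res$penetration <- ifelse(
    res$compartment == "plasma", 1,
    ifelse(res$auc_plasma > 0, res$auc / res$auc_plasma, NA_real_))
  res$auc_plasma <- NULL
  res
}
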