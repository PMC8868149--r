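#' Linear interpolation of a profile
#'
#' The pharmacodynamic metrics use the plain piecewise-linear interpolant on
#' both rising and falling segments (deliberately different from the AUC's
#' log-down rule).
#'
#' @param profile a [conc_profile()].
#' @param t times within the profile span.
#' @return Interpolated concentrations.
#' @export
interp_linear <- function(profile, t) {
  if (any(t < profile$time[1] | t > profile$time[nrow(profile)])) {
    stop("interpolation time outside profile span", call. = FALSE)
  }
  stats::approx(profile$time, profile$conc, xout = t, ties = "ordered")$y
}

#' Cumulative time above the MIC
#'
#' Measure of `{t in [t0, t1] : C(t) > mic}` under the piecewise-linear
#' interpolant, with crossings located exactly on each segment.
#'
#' @param profile a [conc_profile()] covering the window.
#' @param mic threshold concentration, ug/mL (> 0).
#' @param window `c(t0, t1)`, absolute minutes.
#' @return Time above MIC in minutes.
#' @examples
#' p <- conc_profile(c(0, 30, 60), c(0, 8, 2))
#' time_above_mic(p, 4, c(0, 60))  # 35
#' @export
time_above_mic <- function(profile, mic, window) {
  if (mic <= 0) stop("mic must be positive", call. = FALSE)
  .check_window(profile, window[1], window[2])
  tt <- profile$time; cc <- profile$conc
  inner <- tt > window[1] & tt < window[2]
  kt <- c(window[1], tt[inner], window[2])
  kc <- c(interp_linear(profile, window[1]), cc[inner],
          interp_linear(profile, window[2]))
  total <- 0
  for (i in seq_len(length(kt) - 1)) {
    a <- kt[i]; b <- kt[i + 1]; ca <- kc[i]; cb <- kc[i + 1]
    if (ca > mic && cb > mic) {
      total <- total + (b - a)
    } else if (ca > mic || cb > mic) {
      tstar <- a + (mic - ca) / (cb - ca) * (b - a)
      total <- total + if (ca > mic) tstar - a else b - tstar
    }
  }
  total
}

#' Time above MIC as a percentage of the window
#'
#' @param t_above minutes above MIC.
#' @param window_length window length, minutes.
#' @return `100 * t_above / window_length`.
#' @examples
#' pct_time_above_mic(240, 480)  # 50
#' @export
pct_time_above_mic <- function(t_above, window_length) {
  if (any(t_above < 0) || any(t_above > window_length)) {
    stop("t_above must lie in [0, window_length]", call. = FALSE)
  }
  100 * t_above / window_length
}

#' Time to reach a threshold concentration
#'
#' First time at or after the interval's dose start at which the linear
#' interpolant reaches the threshold, reported in minutes from the dose
#' start. Returns 0 when the concentration is already at or above the
#' threshold at the dose start, and `NA` when the threshold is never
#' reached within the profile span.
#'
#' @param profile a [conc_profile()] whose span contains `dose_start`.
#' @param threshold concentration threshold, ug/mL.
#' @param dose_start absolute dose time, minutes.
#' @return Minutes from `dose_start`, or `NA_real_`.
#' @examples
#' p <- conc_profile(c(0, 15), c(0, 53))
#' time_to_threshold(p, 4, 0)  # 15 * 4 / 53 ~= 1.13
#' @export
time_to_threshold <- function(profile, threshold, dose_start = 0) {
  tt <- profile$time; cc <- profile$conc
  n <- length(tt)
  if (dose_start < tt[1] || dose_start > tt[n]) {
    stop("dose_start outside profile span", call. = FALSE)
  }
  c0 <- interp_linear(profile, dose_start)
  if (c0 >= threshold) return(0)
  kt <- c(dose_start, tt[tt > dose_start])
  kc <- c(c0, cc[tt > dose_start])
  for (i in seq_len(length(kt) - 1)) {
    ca <- kc[i]; cb <- kc[i + 1]
    if (cb >= threshold) {
      tstar <- kt[i] + (threshold - ca) / (cb - ca) * (kt[i + 1] - kt[i])
      return(tstar - dose_start)
    }
  }
  NA_real_
}

#' Pharmacodynamic target metrics for a whole cohort
#'
#' Per subject x compartment x dosing interval: fT>MIC (minutes above MIC
#' within the interval's analysis window), %fT>MIC of the window, and the
#' time to reach the MIC from the interval's dose start (TT4 when MIC is
#' 4 ug/mL).
#'
#' @param profiles tibble from [build_cohort_profiles()].
#' @param mic threshold, ug/mL.
#' @param dose_times dose start times, minutes.
#' @param windows tibble from [analysis_windows()].
#' @return tibble with `subject_id`, `compartment`, `interval_index`, `mic`,
#'   `t_above_mic`, `pct_above_mic`, `tt_threshold`.
#' @export
run_pd <- function(profiles, mic = DEFAULT_MIC, dose_times = c(0, 480),
                   windows = analysis_windows(dose_times)) {
  if (mic <= 0) stop("mic must be positive", call. = FALSE)
  combos <- unique(profiles[c("subject_id", "compartment")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    pr <- profile_of(profiles, combos$subject_id[i], combos$compartment[i])
    for (k in seq_len(nrow(windows))) {
      win <- c(windows$win_start[k], windows$win_end[k])
      ta <- time_above_mic(pr, mic, win)
      out[[length(out) + 1]] <- tibble::tibble(
        subject_id = combos$subject_id[i],
        compartment = combos$compartment[i],
        interval_index = windows$interval_index[k], mic = mic,
        t_above_mic = ta,
        pct_above_mic = pct_time_above_mic(ta, diff(win)),
        tt_threshold = time_to_threshold(pr, mic, windows$dose_start[k]))
    }
  }
  dplyr::bind_rows(out)
}
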