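#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Assay and design constants (cefuroxime drug, meropenem calibrator)
DRUG_LOQ <- 0.01        # ug/mL, lower limit of quantification for the drug
CALIBRATOR_LOQ <- 0.05  # ug/mL, LOQ for the internal calibrator
DEFAULT_MIC <- 4        # ug/mL, S. aureus ECOFF for cefuroxime
PERFUSATE_CALIBRATOR <- 5  # ug/mL calibrator added to the perfusate
FLOW_RATE <- 2          # uL/min microdialysis pump flow
MEMBRANE_MM <- c(deadspace = 30, bone = 10)  # catheter membrane lengths

#' Microdialysis sampling schedule for one or more dosing intervals
#'
#' Expands the collection schedule used throughout the package: within each
#' dosing interval, dialysates are pooled over 30-min intervals for the first
#' 240 min and over 60-min intervals from 240 min to the end of the 480-min
#' interval, giving 12 collection intervals per dose (8 + 4).
#'
#' @param dose_times numeric vector of dose start times (minutes from first
#'   dose), default `c(0, 480)`.
#' @param fine_step,fine_span,coarse_step,interval_length schedule geometry in
#'   minutes; defaults reproduce the standard design.
#' @return A tibble with columns `interval_index` (which dosing interval the
#'   collection belongs to), `t_start_min`, `t_end_min` (absolute minutes).
#' @examples
#' sampling_schedule()           # 24 rows: 12 per dosing interval
#' sampling_schedule(dose_times = 0)  # a single dosing interval
#' @export
sampling_schedule <- function(dose_times = c(0, 480), fine_step = 30,
                              fine_span = 240, coarse_step = 60,
                              interval_length = 480) {
  stopifnot(is.numeric(dose_times), length(dose_times) >= 1,
            !is.unsorted(dose_times))
  one <- function(origin, idx) {
    starts <- c(seq(0, fine_span - fine_step, by = fine_step),
                seq(fine_span, interval_length - coarse_step, by = coarse_step))
    ends <- c(starts[-1], interval_length)
    tibble::tibble(interval_index = idx,
                   t_start_min = origin + starts,
                   t_end_min = origin + ends)
  }
  dplyr::bind_rows(lapply(seq_along(dose_times),
                          function(k) one(dose_times[k], k)))
}

#' Midpoint of a sampling interval
#'
#' Interval-averaged dialysate concentrations are assigned to the midpoint of
#' their collection interval, which coincides with the blood-sampling times of
#' the reference design (blood is drawn in the middle of every interval).
#'
#' @param t_start,t_end interval bounds in minutes (vectorised).
#' @return `(t_start + t_end) / 2`.
#' @examples
#' midpoint_time(0, 30)    # 15
#' midpoint_time(240, 300) # 270
#' @export
midpoint_time <- function(t_start, t_end) {
  if (any(t_end <= t_start)) {
    stop("invalid sampling interval: t_end must exceed t_start", call. = FALSE)
  }
  (t_start + t_end) / 2
}

#' Analysis windows for each dosing interval
#'
#' Each dosing interval is analysed from its dose start to the midpoint of the
#' last collection interval before the next dose (450 min after the dose under
#' the standard schedule), the span over which the sampled profile is defined
#' without extrapolation.
#'
#' @param dose_times dose start times, minutes.
#' @param last_obs_offset minutes from a dose to the last observed midpoint
#'   (450 under the standard schedule).
#' @return tibble with `interval_index`, `dose_start`, `win_start`, `win_end`.
#' @export
analysis_windows <- function(dose_times = c(0, 480), last_obs_offset = 450) {
  tibble::tibble(interval_index = seq_along(dose_times),
                 dose_start = dose_times,
                 win_start = dose_times,
                 win_end = dose_times + last_obs_offset)
}
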