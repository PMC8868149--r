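#' Construct a concentration-time profile
#'
#' A profile is a tibble of strictly increasing times (minutes) and
#' non-negative free concentrations (ug/mL) with subject/compartment metadata
#' attached as attributes.
#'
#' @param time,conc numeric vectors of equal length.
#' @param blq logical vector flagging below-LOQ observations (recycled).
#' @param subject_id,compartment metadata.
#' @param anchored logical; `TRUE` when the first point is the (0, 0) anchor.
#' @return tibble of class `conc_profile` with columns `time`, `conc`, `blq`.
#' @export
conc_profile <- function(time, conc, blq = FALSE,
                         subject_id = NA_character_,
                         compartment = NA_character_, anchored = FALSE) {
  stopifnot(length(time) == length(conc))
  if (anyDuplicated(time)) stop("duplicate times in profile", call. = FALSE)
  o <- order(time)
  time <- time[o]; conc <- conc[o]
  blq <- rep_len(blq, length(time))[o]
  if (any(conc < 0)) stop("negative concentration in profile", call. = FALSE)
  if (anchored && (length(time) == 0 || time[1] != 0 || conc[1] != 0)) {
    stop("anchored profile must start at (0, 0)", call. = FALSE)
  }
  out <- tibble::tibble(time = time, conc = conc, blq = blq)
  class(out) <- c("conc_profile", class(out))
  attr(out, "subject_id") <- subject_id
  attr(out, "compartment") <- compartment
  attr(out, "anchored") <- anchored
  out
}

#' Build a recovery-corrected concentration-time profile
#'
#' Dialysate records are recovery-corrected and placed at their collection
#' interval midpoints; plasma records are used at their recorded times with
#' no correction. An optional (0, 0) anchor is prepended for drug-naive
#' subjects at the first dose.
#'
#' @param records data frame of records for a single subject and compartment:
#'   dialysate-shaped (`t_start_min`, `t_end_min`, `drug_conc_ug_ml`) or
#'   plasma-shaped (`time_min`, `free_conc_ug_ml`).
#' @param recovery a one-row recovery estimate (from [catheter_recovery()]);
#'   required for dialysate records, must be `NULL` for plasma.
#' @param anchor_at_zero prepend a (0, 0) point.
#' @return A [conc_profile()].
#' @export
build_profile <- function(records, recovery = NULL, anchor_at_zero = FALSE) {
  is_dialysate <- all(c("t_start_min", "t_end_min", "drug_conc_ug_ml") %in%
                        names(records))
  if (is_dialysate) {
    if (is.null(recovery)) {
      stop("recovery estimate required to build a dialysate profile",
           call. = FALSE)
    }
    time <- midpoint_time(records$t_start_min, records$t_end_min)
    conc <- correct_concentration(records$drug_conc_ug_ml,
                                  recovery$recovery_pct)
    blq <- if ("blq" %in% names(records)) records$blq else FALSE
    subj <- recovery$subject_id
    comp <- recovery$compartment
  } else {
    stopifnot(all(c("time_min", "free_conc_ug_ml") %in% names(records)))
    time <- records$time_min
    conc <- records$free_conc_ug_ml
    blq <- FALSE
    subj <- if ("subject_id" %in% names(records) && nrow(records))
      records$subject_id[1] else NA_character_
    comp <- "plasma"
  }
  if (anchor_at_zero) {
    if (any(time == 0)) stop("cannot anchor: a point at t = 0 already exists",
                             call. = FALSE)
    time <- c(0, time); conc <- c(0, conc); blq <- c(FALSE, rep_len(blq, length(time) - 1))
  }
  conc_profile(time, conc, blq, subject_id = subj, compartment = comp,
               anchored = anchor_at_zero)
}

#' Partition a profile by dosing interval
#'
#' Interval `k` spans `[dose_k, dose_(k+1))` on the absolute clock; the last
#' interval extends to the final observation. Points keep their absolute
#' times (the clock is not reset), and the (0, 0) anchor belongs to interval
#' 1. A point earlier than the first dose is an error.
#'
#' @param profile a [conc_profile()].
#' @param dose_times sorted dose start times, minutes.
#' @return Named list of sub-profiles (`interval_1`, `interval_2`, ...);
#'   empty profiles give empty partitions.
#' @export
split_by_dose_interval <- function(profile, dose_times) {
  stopifnot(!is.unsorted(dose_times))
  if (nrow(profile) && any(profile$time < dose_times[1])) {
    stop("profile point before the first dose", call. = FALSE)
  }
  idx <- findInterval(profile$time, dose_times)
  out <- lapply(seq_along(dose_times), function(k) {
    sub <- profile[idx == k, , drop = FALSE]
    conc_profile(sub$time, sub$conc, sub$blq,
                 subject_id = attr(profile, "subject_id"),
                 compartment = attr(profile, "compartment"),
                 anchored = k == 1 && isTRUE(attr(profile, "anchored")) &&
                   nrow(sub) > 0 && sub$time[1] == 0)
  })
  names(out) <- paste0("interval_", seq_along(dose_times))
  out
}

#' Build profiles for every subject and compartment of a study
#'
#' @param study a [cohort_study()].
#' @param recoveries recovery table from [calibrate_cohort()].
#' @param anchor_at_zero prepend the (0, 0) anchor (drug-naive start).
#' @return tibble with `subject_id`, `compartment`, `time`, `conc`, `blq`.
#' @export
build_cohort_profiles <- function(study, recoveries, anchor_at_zero = TRUE) {
  stopifnot(inherits(study, "cohort_study"))
  rows <- list()
  for (sid in unique(study$doses$subject_id)) {
    pl <- study$plasma[study$plasma$subject_id == sid, ]
    if (nrow(pl)) {
      pr <- build_profile(pl, anchor_at_zero = anchor_at_zero)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sid, compartment = "plasma",
        time = pr$time, conc = pr$conc, blq = pr$blq)
    }
    for (comp in unique(study$dialysates$compartment[
      study$dialysates$subject_id == sid])) {
      rec <- study$dialysates[study$dialysates$subject_id == sid &
                                study$dialysates$compartment == comp, ]
      rcv <- recoveries[recoveries$subject_id == sid &
                          recoveries$compartment == comp, ]
      if (nrow(rcv) != 1) {
        stop("no recovery estimate for ", sid, "/", comp, call. = FALSE)
      }
      pr <- build_profile(rec, rcv, anchor_at_zero = anchor_at_zero)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sid, compartment = comp,
        time = pr$time, conc = pr$conc, blq = pr$blq)
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract one subject-compartment profile from a cohort profile table
#' @param profiles tibble from [build_cohort_profiles()].
#' @param subject_id,compartment selectors.
#' @return A [conc_profile()].
#' @export
profile_of <- function(profiles, subject_id, compartment) {
  p <- profiles[profiles$subject_id == subject_id &
                  profiles$compartment == compartment, ]
  conc_profile(p$time, p$conc, p$blq, subject_id = subject_id,
               compartment = compartment,
               anchored = nrow(p) > 0 && p$time[1] == 0 && p$conc[1] == 0)
}
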