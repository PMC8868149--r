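#' Relative recovery from internal-calibrator loss
#'
#' Retrodialysis by calibrator: a known calibrator concentration is added to
#' the perfusate and its loss across the membrane estimates the fractional
#' exchange, `RR% = 100 * (1 - C_dialysate / C_perfusate)`. The same fraction
#' is assumed for drug gain and calibrator loss.
#'
#' @param c_dial_cal calibrator concentration measured in the dialysate, ug/mL
#'   (vectorised).
#' @param c_perf calibrator concentration in the perfusate, ug/mL (> 0).
#' @return Relative recovery in percent.
#' @examples
#' relative_recovery(1.9, 5)  # 62
#' relative_recovery(0, 5)    # 100 (total loss)
#' @export
relative_recovery <- function(c_dial_cal, c_perf) {
  if (any(c_perf <= 0)) stop("perfusate concentration must be positive",
                             call. = FALSE)
  if (any(c_dial_cal < 0)) stop("dialysate calibrator concentration must be >= 0",
                                call. = FALSE)
  if (any(c_dial_cal > c_perf)) {
    stop("invalid calibration: dialysate calibrator exceeds perfusate ",
         "concentration (negative recovery signals catheter failure)",
         call. = FALSE)
  }
  100 * (1 - c_dial_cal / c_perf)
}

#' Per-catheter relative recovery
#'
#' One time-constant recovery per catheter: the arithmetic mean of per-interval
#' recoveries over all usable calibrator records. Records with calibrator
#' concentration below the calibrator LOQ are excluded; records implying
#' non-positive recovery (calibrator at or above the perfusate level, a
#' physical impossibility attributable to assay noise or catheter failure) are
#' likewise excluded and counted. With no usable record the estimate is
#' returned as not determinable (`recovery_pct = NA`, provenance `"missing"`)
#' so that cohort-level imputation can take over.
#'
#' @param records data frame of dialysate records for one catheter, with a
#'   `calibrator_conc_ug_ml` column.
#' @param c_perf perfusate calibrator concentration, ug/mL.
#' @param calibrator_loq assay LOQ for the calibrator, ug/mL.
#' @param subject_id,compartment identifiers carried into the estimate.
#' @return One-row tibble: `subject_id`, `compartment`, `recovery_pct`,
#'   `n_intervals_used`, `n_excluded`, `provenance` (`"measured"` or
#'   `"missing"`).
#' @export
catheter_recovery <- function(records, c_perf,
                              calibrator_loq = CALIBRATOR_LOQ,
                              subject_id = NA_character_,
                              compartment = NA_character_) {
  cal <- records$calibrator_conc_ug_ml
  usable <- !is.na(cal) & cal >= calibrator_loq & cal < c_perf
  n_excluded <- sum(!usable)
  if (!any(usable)) {
    return(tibble::tibble(subject_id = subject_id, compartment = compartment,
                          recovery_pct = NA_real_, n_intervals_used = 0L,
                          n_excluded = n_excluded, provenance = "missing"))
  }
  rr <- relative_recovery(cal[usable], c_perf)
  tibble::tibble(subject_id = subject_id, compartment = compartment,
                 recovery_pct = mean(rr), n_intervals_used = sum(usable),
                 n_excluded = n_excluded, provenance = "measured")
}

#' Impute a missing catheter recovery from the cohort
#'
#' When a catheter's recovery cannot be determined, the mean of the measured
#' recoveries from the same compartment type across the rest of the cohort is
#' applied, with provenance `"imputed"`.
#'
#' @param estimates tibble of per-catheter estimates (as from
#'   [catheter_recovery()], stacked).
#' @param subject_id,compartment the catheter to impute.
#' @return One-row tibble like [catheter_recovery()]'s.
#' @export
impute_missing_recovery <- function(estimates, subject_id, compartment) {
  pool <- estimates[estimates$compartment == compartment &
                      estimates$provenance == "measured" &
                      !(estimates$subject_id == subject_id), , drop = FALSE]
  if (nrow(pool) == 0) {
    stop("no measured recovery available in compartment '", compartment,
         "': cannot impute", call. = FALSE)
  }
  tibble::tibble(subject_id = subject_id, compartment = compartment,
                 recovery_pct = mean(pool$recovery_pct),
                 n_intervals_used = 0L, n_excluded = 0L,
                 provenance = "imputed")
}

#' Calibrate every catheter in a cohort
#'
#' Runs [catheter_recovery()] per catheter and [impute_missing_recovery()] for
#' any catheter whose recovery is not determinable. Measured estimates are
#' never altered by imputation.
#'
#' @param study a [cohort_study()].
#' @return tibble of recovery estimates, one row per catheter.
#' @export
calibrate_cohort <- function(study) {
  stopifnot(inherits(study, "cohort_study"))
  ca <- study$catheters
  ests <- dplyr::bind_rows(lapply(seq_len(nrow(ca)), function(i) {
    rec <- study$dialysates[study$dialysates$subject_id == ca$subject_id[i] &
                              study$dialysates$compartment == ca$compartment[i], ]
    catheter_recovery(rec, ca$perfusate_calibrator_ug_ml[i],
                      calibrator_loq = study$calibrator_loq,
                      subject_id = ca$subject_id[i],
                      compartment = ca$compartment[i])
  }))
  miss <- which(ests$provenance == "missing")
  for (i in miss) {
    ests[i, ] <- impute_missing_recovery(ests, ests$subject_id[i],
                                         ests$compartment[i])
  }
  ests
}

#' Correct a dialysate concentration for relative recovery
#'
#' Absolute tissue concentration from the dialysate concentration:
#' `C_tissue = C_dialysate / (RR / 100)`.
#'
#' @param c_dial dialysate drug concentration, ug/mL (vectorised).
#' @param recovery_pct relative recovery in percent, in (0, 100].
#' @return Tissue concentration, ug/mL (always `>= c_dial`).
#' @examples
#' correct_concentration(2, 50)   # 4
#' correct_concentration(3.1, 100) # 3.1
#' @export
correct_concentration <- function(c_dial, recovery_pct) {
  if (any(is.na(recovery_pct)) || any(recovery_pct <= 0) ||
      any(recovery_pct > 100)) {
    stop("recovery_pct must lie in (0, 100]", call. = FALSE)
  }
  if (any(c_dial < 0)) stop("dialysate concentration must be >= 0", call. = FALSE)
  c_dial / (recovery_pct / 100)
}
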