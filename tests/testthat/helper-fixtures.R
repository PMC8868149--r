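# Small in-code fixtures: a two-subject study on the standard schedule with
# hand-constructed concentrations.

tiny_study <- function(n_subjects = 2) {
  sched <- sampling_schedule()
  subs <- sprintf("pig%02d", seq_len(n_subjects))
  mk_dial <- function(sid, comp, drug, cal) {
    tibble::tibble(subject_id = sid, compartment = comp,
                   t_start_min = sched$t_start_min,
                   t_end_min = sched$t_end_min,
                   drug_conc_ug_ml = drug, calibrator_conc_ug_ml = cal)
  }
  mids <- midpoint_time(sched$t_start_min, sched$t_end_min)
  dial <- dplyr::bind_rows(lapply(subs, function(s) dplyr::bind_rows(
    mk_dial(s, "deadspace", 10 * exp(-mids / 200), 1.9),
    mk_dial(s, "bone", 4 * exp(-mids / 150), 3.3))))
  plasma <- dplyr::bind_rows(lapply(subs, function(s) tibble::tibble(
    subject_id = s, time_min = mids,
    free_conc_ug_ml = 53 * exp(-((mids - 15) %% 480) / 66))))
  doses <- dplyr::bind_rows(lapply(subs, function(s) tibble::tibble(
    subject_id = s, start_time_min = c(0, 480), dose_mg = 1500,
    infusion_min = 10)))
  cath <- dplyr::bind_rows(lapply(subs, function(s) tibble::tibble(
    subject_id = s, compartment = c("deadspace", "bone"),
    membrane_mm = c(30, 10), flow_ul_min = 2,
    perfusate_calibrator_ug_ml = 5)))
  cohort_study(doses, dial, plasma, cath)
}
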