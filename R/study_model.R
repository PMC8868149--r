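## CSV schemas for the four (plus one optional) study tables
.schema <- list(
  doses      = c("subject_id", "start_time_min", "dose_mg", "infusion_min"),
  dialysates = c("subject_id", "compartment", "t_start_min", "t_end_min",
                 "drug_conc_ug_ml", "calibrator_conc_ug_ml"),
  plasma     = c("subject_id", "time_min", "free_conc_ug_ml"),
  catheters  = c("subject_id", "compartment", "membrane_mm", "flow_ul_min",
                 "perfusate_calibrator_ug_ml"),
  subjects   = c("subject_id", "weight_kg", "weight_group")
)

.read_table <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.schema[[what]], names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s: missing column(s) %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df[.schema[[what]]]
}

#' Assemble a cohort study object
#'
#' Bundles the dosing, dialysate, plasma and catheter tables (and optionally a
#' subject table with weights) into a validated `cohort_study` list. Dialysate
#' drug concentrations below the drug LOQ are flagged (`blq`), never altered.
#'
#' @param doses,dialysates,plasma,catheters data frames following the CSV
#'   schemas (see [load_study()]).
#' @param subjects optional data frame with `subject_id`, `weight_kg`,
#'   `weight_group`.
#' @param mic minimal inhibitory concentration used downstream, ug/mL.
#' @param drug_loq,calibrator_loq assay lower limits of quantification, ug/mL.
#' @return An object of class `cohort_study`.
#' @export
cohort_study <- function(doses, dialysates, plasma, catheters,
                         subjects = NULL, mic = DEFAULT_MIC,
                         drug_loq = DRUG_LOQ, calibrator_loq = CALIBRATOR_LOQ) {
  if (mic <= 0) stop("mic must be positive", call. = FALSE)
  if (nrow(dialysates) == 0) {
    stop("dialysate table contains zero records", call. = FALSE)
  }
  dialysates <- dplyr::arrange(tibble::as_tibble(dialysates),
                               .data$subject_id, .data$compartment,
                               .data$t_start_min)
  dialysates$blq <- dialysates$drug_conc_ug_ml < drug_loq
  # orphan check: every dialysate (subject, compartment) needs a catheter
  key_d <- unique(paste(dialysates$subject_id, dialysates$compartment))
  key_c <- paste(catheters$subject_id, catheters$compartment)
  orphans <- setdiff(key_d, key_c)
  if (length(orphans)) {
    stop("reference error: dialysate records without a catheter: ",
         paste(orphans, collapse = "; "), call. = FALSE)
  }
  structure(list(
    doses = dplyr::arrange(tibble::as_tibble(doses),
                           .data$subject_id, .data$start_time_min),
    dialysates = dialysates,
    plasma = dplyr::arrange(tibble::as_tibble(plasma),
                            .data$subject_id, .data$time_min),
    catheters = dplyr::arrange(tibble::as_tibble(catheters),
                               .data$subject_id, .data$compartment),
    subjects = if (!is.null(subjects)) tibble::as_tibble(subjects),
    mic = mic, drug_loq = drug_loq, calibrator_loq = calibrator_loq
  ), class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat("<cohort_study>\n")
  cat("  subjects:   ", length(unique(x$doses$subject_id)), "\n")
  cat("  doses:      ", nrow(x$doses), "\n")
  cat("  dialysates: ", nrow(x$dialysates),
      sprintf(" (%d BLQ)", sum(x$dialysates$blq)), "\n")
  cat("  plasma:     ", nrow(x$plasma), "\n")
  cat("  MIC:        ", x$mic, "ug/mL\n")
  invisible(x)
}

#' Load a microdialysis study from CSV files
#'
#' Reads the four study tables, checks their headers against the documented
#' schemas, cross-references dialysate records with catheters and normalises
#' all times to minutes from each subject's first dose.
#'
#' Expected columns: `doses.csv` (subject_id, start_time_min, dose_mg,
#' infusion_min), `dialysates.csv` (subject_id, compartment, t_start_min,
#' t_end_min, drug_conc_ug_ml, calibrator_conc_ug_ml), `plasma.csv`
#' (subject_id, time_min, free_conc_ug_ml), `catheters.csv` (subject_id,
#' compartment, membrane_mm, flow_ul_min, perfusate_calibrator_ug_ml).
#'
#' @param dose_csv,dialysate_csv,plasma_csv,catheter_csv file paths.
#' @param subjects_csv optional path to a subject table (weights and weight
#'   groups) used for per-group summaries.
#' @inheritParams cohort_study
#' @return A [cohort_study()] object.
#' @export
load_study <- function(dose_csv, dialysate_csv, plasma_csv, catheter_csv,
                       subjects_csv = NULL, mic = DEFAULT_MIC,
                       drug_loq = DRUG_LOQ, calibrator_loq = CALIBRATOR_LOQ) {
  doses <- .read_table(dose_csv, "doses")
  dialysates <- .read_table(dialysate_csv, "dialysates")
  plasma <- .read_table(plasma_csv, "plasma")
  catheters <- .read_table(catheter_csv, "catheters")
  subjects <- if (!is.null(subjects_csv)) .read_table(subjects_csv, "subjects")

  # normalise times to minutes from each subject's first dose
  t0 <- stats::aggregate(start_time_min ~ subject_id, doses, min)
  names(t0)[2] <- ".t0"
  shift <- function(df, cols) {
    df <- dplyr::left_join(df, t0, by = "subject_id")
    for (cl in cols) df[[cl]] <- df[[cl]] - df$.t0
    df$.t0 <- NULL
    df
  }
  doses <- shift(doses, "start_time_min")
  dialysates <- shift(dialysates, c("t_start_min", "t_end_min"))
  plasma <- shift(plasma, "time_min")

  cohort_study(doses, dialysates, plasma, catheters, subjects,
               mic = mic, drug_loq = drug_loq, calibrator_loq = calibrator_loq)
}

#' Write a cohort study back to CSV files
#'
#' Inverse of [load_study()]: writes `doses.csv`, `dialysates.csv`,
#' `plasma.csv`, `catheters.csv` (and `subjects.csv` when present) under
#' `dir`. Loading the written files reproduces the study record-for-record.
#'
#' @param study a `cohort_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cohort_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (what in names(.schema)) {
    df <- switch(what, doses = study$doses, dialysates = study$dialysates,
                 plasma = study$plasma, catheters = study$catheters,
                 subjects = study$subjects)
    if (is.null(df)) next
    p <- file.path(dir, paste0(what, ".csv"))
    readr::write_csv(df[.schema[[what]]], p, progress = FALSE)
    paths[what] <- p
  }
  invisible(paths)
}

#' Check a study against its content invariants
#'
#' Collects invariant violations (negative concentrations, inverted sampling
#' intervals, non-positive doses or perfusate concentrations, inconsistent
#' BLQ flags) without raising: an empty result means the study is valid.
#'
#' @param study a `cohort_study`.
#' @return tibble with columns `table`, `subject_id`, `row`, `message`;
#'   zero rows when no violation is found.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "cohort_study"))
  v <- list()
  add <- function(table, subject_id, row, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      table = table, subject_id = as.character(subject_id),
      row = as.integer(row), message = message)
  }
  d <- study$doses
  for (i in seq_len(nrow(d))) {
    if (d$start_time_min[i] < 0)
      add("doses", d$subject_id[i], i, "negative dose start time")
    if (d$dose_mg[i] <= 0)
      add("doses", d$subject_id[i], i, "dose_mg must be positive")
    if (d$infusion_min[i] < 0)
      add("doses", d$subject_id[i], i, "negative infusion duration")
  }
  y <- study$dialysates
  for (i in seq_len(nrow(y))) {
    if (y$t_end_min[i] <= y$t_start_min[i])
      add("dialysates", y$subject_id[i], i,
          sprintf("interval [%g, %g) has t_end <= t_start",
                  y$t_start_min[i], y$t_end_min[i]))
    if (is.na(y$drug_conc_ug_ml[i]) || y$drug_conc_ug_ml[i] < 0)
      add("dialysates", y$subject_id[i], i, "negative or missing drug concentration")
    if (!is.na(y$calibrator_conc_ug_ml[i]) && y$calibrator_conc_ug_ml[i] < 0)
      add("dialysates", y$subject_id[i], i, "negative calibrator concentration")
    if (!is.na(y$drug_conc_ug_ml[i]) &&
        !identical(y$blq[i], y$drug_conc_ug_ml[i] < study$drug_loq))
      add("dialysates", y$subject_id[i], i, "blq flag inconsistent with LOQ")
  }
  p <- study$plasma
  for (i in seq_len(nrow(p))) {
    if (p$time_min[i] < 0)
      add("plasma", p$subject_id[i], i, "negative sampling time")
    if (is.na(p$free_conc_ug_ml[i]) || p$free_conc_ug_ml[i] < 0)
      add("plasma", p$subject_id[i], i, "negative or missing free concentration")
  }
  ca <- study$catheters
  for (i in seq_len(nrow(ca))) {
    if (ca$perfusate_calibrator_ug_ml[i] <= 0)
      add("catheters", ca$subject_id[i], i, "perfusate calibrator must be positive")
    if (ca$flow_ul_min[i] <= 0)
      add("catheters", ca$subject_id[i], i, "flow rate must be positive")
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(table = character(), subject_id = character(),
                   row = integer(), message = character())
}

#' Write result tables to CSV with a manifest
#'
#' Writes every data frame in `results` as `<name>.csv` under `out_dir` with
#' deterministic row/column order (as provided; names are written in sorted
#' order), so reruns on identical input produce byte-identical files.
#'
#' @param results named list of data frames.
#' @param out_dir output directory (created if needed).
#' @return tibble manifest: `name`, `path`, `n_rows`.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  rows <- lapply(sort(names(results)), function(nm) {
    df <- results[[nm]]
    stopifnot(is.data.frame(df))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    tibble::tibble(name = nm, path = p, n_rows = nrow(df))
  })
  dplyr::bind_rows(rows)
}
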