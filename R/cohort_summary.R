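#' Mean with a t-distribution confidence interval
#'
#' `mean +/- t_(n-1, 1-alpha/2) * sd / sqrt(n)`. With a single observation
#' the mean is defined but the interval (and SD) are `NA`. `NA` values are
#' dropped and counted.
#'
#' @param values numeric vector.
#' @param level confidence level in (0, 1), default 0.95.
#' @return One-row tibble: `n`, `n_missing`, `mean`, `sd`, `ci_low`,
#'   `ci_high`.
#' @export
group_mean_ci <- function(values, level = 0.95) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  stopifnot(level > 0, level < 1)
  n_missing <- sum(is.na(values))
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no non-missing values", call. = FALSE)
  m <- mean(values)
  if (n == 1) {
    return(tibble::tibble(n = 1L, n_missing = n_missing, mean = m,
                          sd = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_))
  }
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  tibble::tibble(n = as.integer(n), n_missing = n_missing, mean = m, sd = s,
                 ci_low = m - half, ci_high = m + half)
}

#' Paired two-sided comparison of two dosing intervals
#'
#' Two-sided p-value from the paired t statistic on within-subject
#' differences. Pairs with a missing value are dropped; at least two complete
#' pairs are required. Identical pairs (all differences zero) give p = 1;
#' non-zero constant differences give p = 0 in the degenerate zero-variance
#' limit.
#'
#' @param x1,x2 per-subject metric in interval 1 and interval 2 (same order).
#' @return Two-sided p-value.
#' @export
compare_intervals <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  ok <- !is.na(x1) & !is.na(x2)
  d <- x2[ok] - x1[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) == 0) 1 else 0)
  tstat <- mean(d) / (s / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

.mean_ci_row <- function(values, level, label_cols) {
  dplyr::bind_cols(label_cols, group_mean_ci(values, level))
}

## NA instead of an error when fewer than 2 complete pairs are available,
## so single-subject cohorts still summarise.
.safe_compare <- function(x1, x2) {
  if (sum(!is.na(x1) & !is.na(x2)) < 2) return(NA_real_)
  compare_intervals(x1, x2)
}

#' Cohort summary tables
#'
#' Aggregates the per-subject NCA and PD results into four tables mirroring
#' a two-dose multi-compartment study report:
#' \describe{
#'   \item{table1}{per weight group: deadspace fT>MIC and deadspace
#'     penetration by dosing interval (collapses to one pooled column when
#'     no grouping is available);}
#'   \item{table2}{pooled fT>MIC minutes and %fT>MIC per compartment and
#'     interval, with per-subject interval sums as the total and a
#'     whole-window recomputation where supplied;}
#'   \item{table3}{time to reach the MIC threshold, mean (SD);}
#'   \item{table4}{AUC, Cmax (mean, CI), Tmax, half-life (mean, SD) and
#'     penetration per compartment and interval.}
#' }
#' Interval contrasts are paired two-sided t-tests on within-subject
#' differences; compartment contrasts are paired t-tests on per-subject
#' totals (all compartments are within-subject). This is a deliberate,
#' simpler replacement for a mixed-model analysis and is flagged in `meta`.
#'
#' @param nca tibble from [run_nca()].
#' @param pd tibble from [run_pd()].
#' @param subjects optional tibble with `subject_id`, `weight_group`.
#' @param pd_whole optional tibble from [run_pd()] computed on the whole
#'   observation span (single window), reported alongside the interval sums.
#' @param level confidence level for intervals.
#' @return Named list: `table1`, `table2`, `table3`, `table4`,
#'   `comparisons`, `meta`.
#' @export
summarize_cohort <- function(nca, pd, subjects = NULL, pd_whole = NULL,
                             level = 0.95) {
  comps <- unique(pd$compartment)
  ivs <- sort(unique(pd$interval_index))

  ## --- table 2: fT>MIC minutes and percent ---
  t2 <- list()
  for (cm in comps) {
    sub <- pd[pd$compartment == cm, ]
    for (k in ivs) {
      s <- sub[sub$interval_index == k, ]
      t2[[length(t2) + 1]] <- .mean_ci_row(
        s$t_above_mic, level,
        tibble::tibble(compartment = cm, metric = "ft_above_mic_min",
                       interval = as.character(k)))
      t2[[length(t2) + 1]] <- .mean_ci_row(
        s$pct_above_mic, level,
        tibble::tibble(compartment = cm, metric = "pct_ft_above_mic",
                       interval = as.character(k)))
    }
    tot <- stats::aggregate(t_above_mic ~ subject_id, sub, sum)
    ptot <- stats::aggregate(pct_above_mic ~ subject_id, sub, mean)
    t2[[length(t2) + 1]] <- .mean_ci_row(
      tot$t_above_mic, level,
      tibble::tibble(compartment = cm, metric = "ft_above_mic_min",
                     interval = "total"))
    t2[[length(t2) + 1]] <- .mean_ci_row(
      ptot$pct_above_mic, level,
      tibble::tibble(compartment = cm, metric = "pct_ft_above_mic",
                     interval = "total"))
    if (!is.null(pd_whole)) {
      w <- pd_whole[pd_whole$compartment == cm, ]
      t2[[length(t2) + 1]] <- .mean_ci_row(
        w$t_above_mic, level,
        tibble::tibble(compartment = cm, metric = "ft_above_mic_min",
                       interval = "whole_window"))
    }
  }
  table2 <- dplyr::bind_rows(t2)

  ## --- table 3: time to threshold ---
  t3 <- list()
  for (cm in comps) for (k in ivs) {
    s <- pd[pd$compartment == cm & pd$interval_index == k, ]
    t3[[length(t3) + 1]] <- .mean_ci_row(
      s$tt_threshold, level,
      tibble::tibble(compartment = cm, metric = "tt_threshold_min",
                     interval = as.character(k)))
  }
  table3 <- dplyr::bind_rows(t3)

  ## --- table 4: PK parameters ---
  t4 <- list()
  pk_metrics <- c(auc = "auc", cmax = "cmax", tmax = "tmax",
                  t_half = "t_half", penetration = "penetration")
  for (cm in unique(nca$compartment)) for (k in ivs) {
    s <- nca[nca$compartment == cm & nca$interval_index == k, ]
    for (mname in names(pk_metrics)) {
      if (mname == "penetration" && cm == "plasma") next
      t4[[length(t4) + 1]] <- .mean_ci_row(
        s[[pk_metrics[mname]]], level,
        tibble::tibble(compartment = cm, metric = mname,
                       interval = as.character(k)))
    }
  }
  table4 <- dplyr::bind_rows(t4)

  ## --- table 1: per weight group (deadspace focus) ---
  if (!is.null(subjects) && "weight_group" %in% names(subjects)) {
    grp <- subjects[c("subject_id", "weight_group")]
  } else {
    grp <- tibble::tibble(subject_id = unique(pd$subject_id),
                          weight_group = "pooled")
  }
  t1 <- list()
  ds_pd <- dplyr::left_join(pd[pd$compartment == "deadspace", ], grp,
                            by = "subject_id")
  ds_nca <- dplyr::left_join(nca[nca$compartment == "deadspace", ], grp,
                             by = "subject_id")
  for (g in unique(grp$weight_group)) for (k in ivs) {
    s <- ds_pd[ds_pd$weight_group == g & ds_pd$interval_index == k, ]
    if (nrow(s)) {
      t1[[length(t1) + 1]] <- .mean_ci_row(
        s$t_above_mic, level,
        tibble::tibble(weight_group = g, metric = "deadspace_ft_above_mic_min",
                       interval = as.character(k)))
    }
    s <- ds_nca[ds_nca$weight_group == g & ds_nca$interval_index == k, ]
    if (nrow(s)) {
      t1[[length(t1) + 1]] <- .mean_ci_row(
        s$penetration, level,
        tibble::tibble(weight_group = g, metric = "deadspace_penetration",
                       interval = as.character(k)))
    }
  }
  table1 <- dplyr::bind_rows(t1)

  ## --- paired comparisons ---
  cmp <- list()
  if (length(ivs) >= 2) {
    wide <- function(df, value) {
      tidyr::pivot_wider(df[c("subject_id", "compartment", "interval_index",
                              value)],
                         names_from = "interval_index",
                         values_from = dplyr::all_of(value))
    }
    for (cm in comps) {
      w <- wide(pd[pd$compartment == cm, ], "t_above_mic")
      cmp[[length(cmp) + 1]] <- tibble::tibble(
        comparison = "interval_1_vs_2", metric = "ft_above_mic_min",
        compartment = cm, p_value = .safe_compare(w$`1`, w$`2`))
      w <- wide(pd[pd$compartment == cm, ], "tt_threshold")
      cmp[[length(cmp) + 1]] <- tibble::tibble(
        comparison = "interval_1_vs_2", metric = "tt_threshold_min",
        compartment = cm,
        p_value = .safe_compare(w$`1`, w$`2`))
    }
    for (cm in unique(nca$compartment)) {
      for (mname in c("auc", "cmax", "tmax", "t_half")) {
        w <- wide(nca[nca$compartment == cm, ], mname)
        cmp[[length(cmp) + 1]] <- tibble::tibble(
          comparison = "interval_1_vs_2", metric = mname, compartment = cm,
          p_value = .safe_compare(w$`1`, w$`2`))
      }
    }
  }
  # compartment contrasts on per-subject fT>MIC totals (paired within subject)
  tots <- stats::aggregate(t_above_mic ~ subject_id + compartment, pd, sum)
  pairs <- utils::combn(comps, 2, simplify = FALSE)
  for (pr in pairs) {
    a <- tots[tots$compartment == pr[1], ]
    b <- tots[tots$compartment == pr[2], ]
    m <- merge(a, b, by = "subject_id")
    if (nrow(m) >= 2) {
      cmp[[length(cmp) + 1]] <- tibble::tibble(
        comparison = paste0(pr[1], "_vs_", pr[2]),
        metric = "ft_above_mic_total_min", compartment = NA_character_,
        p_value = .safe_compare(m$t_above_mic.x, m$t_above_mic.y))
    }
  }
  comparisons <- if (length(cmp)) dplyr::bind_rows(cmp) else
    tibble::tibble(comparison = character(), metric = character(),
                   compartment = character(), p_value = numeric())

  list(table1 = table1, table2 = table2, table3 = table3, table4 = table4,
       comparisons = comparisons,
       meta = tibble::tibble(
         note = paste("Interval and compartment contrasts are paired",
                      "two-sided t-tests on within-subject differences,",
                      "substituting for a mixed-model ANOVA."),
         confidence_level = level))
}
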