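test_that("relative recovery follows the calibrator-loss formula", {
  expect_equal(relative_recovery(1.9, 5), 62)
  expect_equal(relative_recovery(5, 5), 0)
  expect_equal(relative_recovery(0, 5), 100)
  expect_error(relative_recovery(5.1, 5), "catheter failure")
  expect_error(relative_recovery(1, 0), "positive")
})

test_that("relative recovery is strictly decreasing in the dialysate calibrator", {
  cal <- seq(0, 5, by = 0.25)
  rr <- relative_recovery(cal, 5)
  expect_true(all(diff(rr) < 0))
})

test_that("catheter recovery averages usable intervals and excludes below-LOQ records", {
  rec <- function(cal) tibble::tibble(calibrator_conc_ug_ml = cal)
  est <- catheter_recovery(rec(c(1.9, 1.9, 1.9)), 5, subject_id = "p1",
                           compartment = "deadspace")
  expect_equal(est$recovery_pct, 62)
  expect_equal(est$n_intervals_used, 3L)
  expect_equal(est$provenance, "measured")
  est <- catheter_recovery(rec(c(1.5, 2.5)), 5)
  expect_equal(est$recovery_pct, 60)
  # records below the calibrator LOQ are dropped from the mean
  est <- catheter_recovery(rec(c(1.5, 2.5, 0.04)), 5)
  expect_equal(est$recovery_pct, 60)
  expect_equal(est$n_excluded, 1L)
  # nothing usable -> not determinable
  est <- catheter_recovery(rec(c(0.01, 0.04)), 5)
  expect_true(is.na(est$recovery_pct))
  expect_equal(est$provenance, "missing")
})

test_that("missing recoveries are imputed from same-compartment means", {
  ests <- tibble::tibble(
    subject_id = c("p1", "p2", "p3"), compartment = "bone",
    recovery_pct = c(30, 38, NA), n_intervals_used = c(24L, 24L, 0L),
    n_excluded = 0L, provenance = c("measured", "measured", "missing"))
  imp <- impute_missing_recovery(ests, "p3", "bone")
  expect_equal(imp$recovery_pct, 34)
  expect_equal(imp$provenance, "imputed")
  # single measured donor
  one <- ests[c(1, 3), ]
  one$recovery_pct[1] <- 34
  expect_equal(impute_missing_recovery(one, "p3", "bone")$recovery_pct, 34)
  # no measured donor anywhere
  none <- ests
  none$provenance <- "missing"
  expect_error(impute_missing_recovery(none, "p3", "bone"), "cannot impute")
})

test_that("imputation never changes measured estimates in a complete cohort", {
  st <- tiny_study()
  ests <- calibrate_cohort(st)
  expect_true(all(ests$provenance == "measured"))
  expect_equal(ests$recovery_pct[ests$compartment == "deadspace"],
               rep(62, 2))
  expect_equal(ests$recovery_pct[ests$compartment == "bone"], rep(34, 2))
})

test_that("calibrate_cohort imputes a dead calibrator channel from the cohort", {
  st <- tiny_study(n_subjects = 3)
  dead <- st$dialysates$subject_id == "pig02" &
    st$dialysates$compartment == "bone"
  st$dialysates$calibrator_conc_ug_ml[dead] <- 0.01  # below calibrator LOQ
  ests <- calibrate_cohort(st)
  got <- ests[ests$subject_id == "pig02" & ests$compartment == "bone", ]
  expect_equal(got$provenance, "imputed")
  expect_equal(got$recovery_pct, 34)  # mean of the remaining bone recoveries
})

test_that("concentration correction inverts the recovery fraction", {
  expect_equal(correct_concentration(2, 50), 4)
  expect_equal(correct_concentration(3.1, 100), 3.1)
  expect_equal(correct_concentration(0, 62), 0)
  expect_true(all(correct_concentration(c(1, 2), 40) >= c(1, 2)))
  expect_error(correct_concentration(1, 0), "\\(0, 100]")
  expect_error(correct_concentration(1, NA_real_), "\\(0, 100]")
})

test_that("recovery correction round-trips exactly on noise-free records", {
  # a noise-free simulated catheter: corrected concentration must equal the
  # true interval-average concentration to machine precision
  p <- default_params_calibrated(75, noise_cv = 0)
  sim <- simulate_subject(p)
  st <- cohort_study(sim$records$doses, sim$records$dialysates,
                     sim$records$plasma, sim$records$catheters)
  ests <- calibrate_cohort(st)
  for (comp in c("deadspace", "bone")) {
    rec <- st$dialysates[st$dialysates$compartment == comp, ]
    rcv <- ests[ests$compartment == comp, ]
    expect_equal(rcv$recovery_pct, p$recovery_true[[comp]])
    corrected <- correct_concentration(rec$drug_conc_ug_ml, rcv$recovery_pct)
    true_avg <- rec$drug_conc_ug_ml / (p$recovery_true[[comp]] / 100)
    expect_equal(corrected, true_avg, tolerance = 1e-12)
  }
})
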