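test_that("linear-up/log-down AUC handles rising, falling and flat segments", {
  up <- conc_profile(c(0, 10), c(0, 10))
  expect_equal(auc_lin_up_log_down(up, 0, 10), 50)
  # falling segment: log trapezoid is exact for the exponential interpolant;
  # frozen value cross-checked against fine-grid Simpson integration
  down <- conc_profile(c(0, 10), c(10, 5))
  expect_equal(oracle_auc(c(0, 10), c(10, 5), 0, 10), 50 / log(2),
               tolerance = 1e-9)
  expect_equal(auc_lin_up_log_down(down, 0, 10), 72.134752044,
               tolerance = 1e-9)
  mixed <- conc_profile(c(0, 10, 20, 30), c(0, 10, 5, 5))
  expect_equal(auc_lin_up_log_down(mixed, 0, 30), 50 + 50 / log(2) + 50,
               tolerance = 1e-9)
  expect_equal(auc_lin_up_log_down(mixed, 0, 30), 172.134752,
               tolerance = 1e-6)
  expect_error(auc_lin_up_log_down(up, 10, 0), "exceed")
  expect_error(auc_lin_up_log_down(conc_profile(5, 1), 0, 5), "2 points")
  expect_error(auc_lin_up_log_down(up, 0, 11), "span")
})

test_that("AUC is additive over adjacent windows", {
  set.seed(101)
  for (i in 1:25) {
    pr <- random_profile(8, span = 90)
    t0 <- pr$time[1]; t2 <- pr$time[nrow(pr)]
    t1 <- runif(1, t0, t2)
    lhs <- auc_lin_up_log_down(pr, t0, t2)
    rhs <- auc_lin_up_log_down(pr, t0, t1) +
      auc_lin_up_log_down(pr, t1, t2)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("log-trapezoid AUC is exact on mono-exponential declines", {
  lam <- 0.015
  t <- c(0, 20, 50, 90, 140, 200)
  pr <- conc_profile(t, 40 * exp(-lam * t))
  analytic <- 40 / lam * (exp(-lam * 5) - exp(-lam * 180))
  expect_equal(auc_lin_up_log_down(pr, 5, 180), analytic, tolerance = 1e-9)
})

test_that("AUC matches fine-grid integration of the segment interpolant", {
  set.seed(202)
  for (i in 1:50) {
    pr <- random_profile()
    t0 <- pr$time[1]; t1 <- pr$time[nrow(pr)]
    got <- auc_lin_up_log_down(pr, t0, t1)
    want <- oracle_auc(pr$time, pr$conc, t0, t1)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("cmax/tmax take the earliest observed maximum relative to the dose", {
  pr <- conc_profile(c(0, 15, 45), c(0, 53, 30))
  expect_equal(cmax_tmax(pr, c(0, 480)), list(cmax = 53, tmax = 15))
  tie <- conc_profile(c(30, 60), c(10, 10))
  expect_equal(cmax_tmax(tie, c(0, 480))$tmax, 30)
  late <- conc_profile(495, 7)
  expect_equal(cmax_tmax(late, c(480, 960), dose_start = 480),
               list(cmax = 7, tmax = 15))
  expect_error(cmax_tmax(pr, c(100, 200)), "no points")
})

test_that("terminal rate regression matches the closed-form OLS slope", {
  t <- c(0, 30, 60, 90)
  pr <- conc_profile(t, 16 * 2^(-t / 30))
  lam <- terminal_lambda(pr, c(0, 480))
  expect_equal(lam$lambda_eq, log(2) / 30, tolerance = 1e-12)
  expect_equal(lam$n_lambda_points, 3L)
  expect_equal(half_life(lam$lambda_eq), 30)
  # noisy flat tail: sign rule decides, oracle gives the slope
  pr2 <- conc_profile(c(0, 10, 20, 30, 40), c(20, 10, 9, 10, 9))
  sl <- oracle_ols_slope(c(10, 20, 30, 40), c(10, 9, 10, 9))
  lam2 <- terminal_lambda(pr2, c(0, 480))
  if (sl >= 0) {
    expect_true(is.na(lam2$lambda_eq))
    expect_equal(lam2$reason, "non-negative slope")
  } else {
    expect_equal(lam2$lambda_eq, -sl, tolerance = 1e-12)
  }
  # too few post-peak points
  lam3 <- terminal_lambda(conc_profile(c(0, 10, 20), c(5, 3, 2)), c(0, 480))
  expect_true(is.na(lam3$lambda_eq))
  expect_equal(lam3$reason, "insufficient points")
})

test_that("half-life is undefined for non-positive or missing rates", {
  expect_equal(half_life(log(2) / 46), 46)
  expect_equal(half_life(0.00693147), 100, tolerance = 1e-5)
  expect_true(is.na(half_life(NA_real_)))
  expect_true(is.na(half_life(-0.01)))
})

test_that("penetration ratio reproduces the reported exposure ratios", {
  expect_equal(round(penetration_ratio(4147, 2521), 2), 1.64)
  expect_equal(round(penetration_ratio(1886, 2521), 2), 0.75)
  expect_equal(penetration_ratio(1234, 1234), 1)
  expect_error(penetration_ratio(1, 0), "positive")
})

test_that("terminal fit recovers the true half-life exactly on clean tails", {
  lam_true <- log(2) / 46
  t <- seq(15, 450, by = 45)
  pr <- conc_profile(c(0, t), c(0, 53 * exp(-lam_true * (t - 15))))
  est <- terminal_lambda(pr, c(0, 480))
  expect_equal(half_life(est$lambda_eq), 46, tolerance = 1e-9)
})

test_that("BLQ values after the last quantifiable point count as zero in AUC", {
  pr <- conc_profile(c(0, 30, 60, 90), c(0, 8, 0.005, 0.004),
                     blq = c(FALSE, FALSE, TRUE, TRUE))
  row <- nca_interval(pr, c(0, 90))
  # the flagged tail contributes the linear ramp down to zero and nothing after
  expected <- auc_lin_up_log_down(
    conc_profile(c(0, 30, 60, 90), c(0, 8, 0, 0)), 0, 90)
  expect_equal(row$auc, expected)
  # flagged values are never the reported Cmax and are excluded from lambda
  expect_equal(row$cmax, 8)
})
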