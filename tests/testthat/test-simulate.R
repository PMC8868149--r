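test_that("parameter validation rejects impossible study settings", {
  expect_error(sim_params(weight_kg = -5), "positive")
  expect_error(sim_params(noise_cv = -0.1), "negative")
  expect_error(sim_params(recovery_true = c(deadspace = 120, bone = 30)),
               "recoveries")
})

test_that("noise-free records at full recovery equal the true interval averages", {
  p <- sim_params(noise_cv = 0, recovery_true = c(deadspace = 100, bone = 100))
  sim <- simulate_subject(p)
  g <- sim$truth$grid
  sched <- sampling_schedule()
  for (comp in c("deadspace", "bone")) {
    rec <- sim$records$dialysates[sim$records$dialysates$compartment == comp, ]
    # independent interval average: trapezoid on the output grid
    avg <- vapply(seq_len(nrow(sched)), function(i) {
      sel <- g$time >= sched$t_start_min[i] & g$time <= sched$t_end_min[i]
      ts <- g$time[sel]; cs <- g[[comp]][sel]
      sum((cs[-1] + cs[-length(cs)]) / 2 * diff(ts)) / (max(ts) - min(ts))
    }, numeric(1))
    expect_equal(rec$drug_conc_ug_ml, avg, tolerance = 1e-6)
  }
  # calibrator at 100% recovery is fully lost to the tissue
  expect_true(all(sim$records$dialysates$calibrator_conc_ug_ml == 0))
})

test_that("the kinetic system is linear in dose", {
  p1 <- sim_params(noise_cv = 0)
  p2 <- sim_params(noise_cv = 0, dose_per_kg = 40)
  s1 <- simulate_subject(p1); s2 <- simulate_subject(p2)
  for (comp in c("plasma", "deadspace", "bone")) {
    expect_equal(s2$truth$grid[[comp]], 2 * s1$truth$grid[[comp]],
                 tolerance = 1e-12)
  }
  expect_equal(s2$records$plasma$free_conc_ug_ml,
               2 * s1$records$plasma$free_conc_ug_ml, tolerance = 1e-12)
})

test_that("without consolidation and with full washout the intervals superpose", {
  # fast elimination so the first dose is fully washed out by 480 min
  p <- sim_params(noise_cv = 0, tauc = Inf, cl_per_kg = 0.02,
                  kout = 0.08, kin = 0.06, cl_d0 = 1.5)
  sim <- simulate_subject(p)
  g <- sim$truth$grid
  i1 <- g$time <= 480
  shifted <- g[g$time >= 480 & g$time <= 960, ]
  for (comp in c("plasma", "deadspace", "bone")) {
    a <- g[[comp]][i1]
    b <- shifted[[comp]]
    expect_equal(b, a[seq_along(b)], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("solver matches matrix-exponential propagation on constant-coefficient segments", {
  p <- sim_params(noise_cv = 0, tauc = Inf)
  sim <- simulate_subject(p)
  g <- sim$truth$grid
  kd <- p$cl_d0 / p$vd_ml
  M <- rbind(c(-(p$cl + p$q) / p$vc, p$q / p$vp, 0, 0),
             c(p$q / p$vc, -p$q / p$vp, 0, 0),
             c(kd / p$vc, 0, -kd, 0),
             c(p$kin / p$vc, 0, 0, -p$kout))
  rate <- p$dose_per_kg * p$weight_kg / p$infusion_min
  y <- c(0, 0, 0, 0)
  breaks <- c(0, 10, 480, 490, 960)
  on <- c(TRUE, FALSE, TRUE, FALSE)
  for (i in seq_len(4)) {
    b <- c(if (on[i]) rate else 0, 0, 0, 0)
    yss <- solve(M, -b)
    E <- as.matrix(Matrix::expm(M * (breaks[i + 1] - breaks[i])))
    y <- as.numeric(E %*% (y - yss) + yss)
    row <- g[g$time == breaks[i + 1], ]
    got <- c(row$amt_central, row$amt_peripheral, row$deadspace, row$bone)
    expect_equal(got, y, tolerance = 1e-8)
  }
})

test_that("consolidating deadspace agrees with an adaptive ODE solver", {
  p <- sim_params(noise_cv = 0)
  sim <- simulate_subject(p)
  rate <- p$dose_per_kg * p$weight_kg / p$infusion_min
  rhs <- function(t, y, parms) {
    inf <- sum(vapply(p$dose_times, function(d)
      (t >= d && t < d + p$infusion_min) * rate, numeric(1)))
    cc <- y[1] / p$vc
    kd <- p$cl_d0 / p$vd_ml * exp(-t / p$tauc)
    list(c(inf - (p$cl + p$q) / p$vc * y[1] + p$q / p$vp * y[2],
           p$q / p$vc * y[1] - p$q / p$vp * y[2],
           kd * (cc - y[3]),
           p$kin * cc - p$kout * y[4]))
  }
  times <- c(0, 60, 240, 477, 600, 960)
  out <- deSolve::lsoda(c(0, 0, 0, 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  g <- sim$truth$grid
  for (i in seq_along(times)) {
    row <- g[g$time == times[i], ]
    expect_equal(row$deadspace, unname(out[i, 4]), tolerance = 1e-6)
    expect_equal(row$bone, unname(out[i, 5]), tolerance = 1e-6)
    expect_equal(row$plasma, unname(out[i, 2]) / p$vc, tolerance = 1e-6)
  }
})

test_that("plasma drug mass never increases once an infusion has ended", {
  p <- sim_params(noise_cv = 0)
  g <- simulate_subject(p)$truth$grid
  total <- g$amt_central + g$amt_peripheral
  outside <- !((g$time >= 0 & g$time <= 10) |
                 (g$time >= 480 & g$time <= 490))
  expect_true(all(diff(total)[outside[-1]] <= 1e-9))
})

test_that("stronger consolidation monotonically delays the second interval", {
  # below tauc ~ 180 the interval-2 peak is dominated by interval-1
  # carryover and Tmax is no longer a monotone index of consolidation
  taus <- c(180, 300, 480, 960)
  th2 <- numeric(length(taus)); tm2 <- numeric(length(taus))
  for (i in seq_along(taus)) {
    p <- sim_params(noise_cv = 0, tauc = taus[i])
    m <- simulate_subject(p)$truth$metrics
    ds2 <- m[m$compartment == "deadspace" & m$interval_index == 2, ]
    th2[i] <- ds2$t_half; tm2[i] <- ds2$tmax
  }
  # decreasing tauc (stronger consolidation) lengthens T1/2 and delays Tmax
  expect_true(all(diff(th2) < 0))
  expect_true(all(diff(tm2) <= 0))
})

test_that("cohort simulation is reproducible and honours the design", {
  a <- simulate_cohort(seed = 11)
  b <- simulate_cohort(seed = 11)
  expect_identical(a$study$dialysates, b$study$dialysates)
  expect_identical(a$study$subjects, b$study$subjects)
  expect_equal(length(unique(a$study$doses$subject_id)), 18)
  expect_equal(nrow(a$study$dialysates), 18 * 2 * 24)
  expect_setequal(unique(a$study$subjects$weight_group),
                  c("53-57", "73-77", "93-97"))
  expect_true(all(a$study$subjects$weight_kg >= 53 &
                    a$study$subjects$weight_kg <= 97))
})

test_that("zero between-subject variability makes same-weight subjects identical", {
  co <- simulate_cohort(n_per_group = 3, weight_bands = list(c(75, 75)),
                        seed = 5,
                        bsv_cv = c(cl = 0, v = 0, cl_d0 = 0, tauc = 0,
                                   kin = 0),
                        recovery_sd = c(deadspace = 0, bone = 0),
                        noise_cv = 0)
  d <- co$study$dialysates
  ref <- d[d$subject_id == "pig01", c("drug_conc_ug_ml",
                                      "calibrator_conc_ug_ml")]
  for (s in c("pig02", "pig03")) {
    expect_equal(d[d$subject_id == s, c("drug_conc_ug_ml",
                                        "calibrator_conc_ug_ml")],
                 ref, ignore_attr = TRUE)
  }
})
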