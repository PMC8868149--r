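test_that("schedule expansion gives 12 collection intervals per dose, 24 overall", {
  sched <- sampling_schedule()
  expect_equal(nrow(sched), 24)
  expect_equal(sum(sched$interval_index == 1), 12)
  expect_equal(sum(sched$t_end_min - sched$t_start_min == 30), 16)
  expect_equal(sum(sched$t_end_min - sched$t_start_min == 60), 8)
  # intervals tile each 8-h dosing interval without gaps
  s1 <- sched[sched$interval_index == 1, ]
  expect_equal(s1$t_start_min[-1], s1$t_end_min[-12])
  expect_equal(range(s1$t_start_min, s1$t_end_min), c(0, 480))
})

test_that("write_study / load_study round-trips a study record-for-record", {
  st <- tiny_study()
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  st2 <- load_study(paths["doses"], paths["dialysates"], paths["plasma"],
                    paths["catheters"])
  for (tab in c("doses", "dialysates", "plasma", "catheters")) {
    expect_equal(as.data.frame(st2[[tab]]), as.data.frame(st[[tab]]),
                 ignore_attr = TRUE)
  }
  expect_equal(nrow(st2$dialysates[st2$dialysates$subject_id == "pig01" &
                                     st2$dialysates$compartment == "bone", ]),
               24)
})

test_that("load_study normalises times to minutes from the first dose", {
  st <- tiny_study()
  st$doses$start_time_min <- st$doses$start_time_min + 100
  st$dialysates$t_start_min <- st$dialysates$t_start_min + 100
  st$dialysates$t_end_min <- st$dialysates$t_end_min + 100
  st$plasma$time_min <- st$plasma$time_min + 100
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  st2 <- load_study(paths["doses"], paths["dialysates"], paths["plasma"],
                    paths["catheters"])
  expect_equal(min(st2$doses$start_time_min), 0)
  expect_equal(min(st2$dialysates$t_start_min), 0)
})

test_that("schema and reference errors are specific", {
  st <- tiny_study()
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  # missing column is named
  d <- readr::read_csv(paths["doses"], show_col_types = FALSE)
  readr::write_csv(d[setdiff(names(d), "dose_mg")], paths["doses"])
  expect_error(load_study(paths["doses"], paths["dialysates"],
                          paths["plasma"], paths["catheters"]),
               "dose_mg")
  # empty dialysate table
  st2 <- tiny_study()
  expect_error(cohort_study(st2$doses, st2$dialysates[0, ], st2$plasma,
                            st2$catheters),
               "zero records")
  # orphan dialysate record (no catheter for the compartment)
  orphan <- st2$dialysates
  orphan$compartment[1] <- "muscle"
  expect_error(cohort_study(st2$doses, orphan, st2$plasma, st2$catheters),
               "reference error")
})

test_that("validate_study reports violations without raising", {
  st <- tiny_study()
  expect_equal(nrow(validate_study(st)), 0)
  st$dialysates$t_end_min[3] <- st$dialysates$t_start_min[3] - 1
  st$plasma$free_conc_ug_ml[2] <- -0.5
  v <- validate_study(st)
  expect_equal(nrow(v), 2)
  expect_match(v$message[v$table == "dialysates"], "t_end <= t_start")
  expect_match(v$message[v$table == "plasma"], "negative")
  expect_equal(v$row[v$table == "dialysates"], 3L)
})

test_that("write_results is deterministic and handles empty tables", {
  dir <- withr::local_tempdir()
  res <- list(nca = tibble::tibble(subject_id = "pig01",
                                   compartment = c("plasma", "deadspace",
                                                   "bone"),
                                   auc = c(1, 2, 3)),
              empty = tibble::tibble(a = numeric(), b = character()))
  man <- write_results(res, dir)
  expect_setequal(man$name, c("nca", "empty"))
  expect_equal(man$n_rows[man$name == "empty"], 0)
  expect_equal(readLines(file.path(dir, "empty.csv")), "a,b")
  first <- readLines(file.path(dir, "nca.csv"))
  write_results(res, dir)
  expect_identical(readLines(file.path(dir, "nca.csv")), first)
})
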