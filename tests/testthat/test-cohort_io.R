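test_that("a valid fixture round-trips through write_cohort/read_cohort", {
  co <- tiny_cohort()
  expect_equal(n_subjects(co), 3L)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(file.path(dir, "subjects.csv"),
                      file.path(dir, "measurements.csv"),
                      file.path(dir, "events.csv"))
  expect_equal(back$subjects, co$subjects)
  expect_equal(back$measurements, co$measurements, tolerance = 1e-12)
  expect_equal(back$events, co$events, tolerance = 1e-12)
})

test_that("round-trip holds on a generated 200-subject cohort", {
  g <- generate_cohort(default_paper_config(), 200, seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, dir)
  back <- read_cohort(file.path(dir, "subjects.csv"),
                      file.path(dir, "measurements.csv"),
                      file.path(dir, "events.csv"))
  expect_equal(back$subjects, g$cohort$subjects, tolerance = 1e-10)
  expect_equal(back$measurements, g$cohort$measurements, tolerance = 1e-10)
  expect_equal(back$events, g$cohort$events, tolerance = 1e-10)
})

test_that("an empty cohort writes three header-only CSVs", {
  co <- cohort(tiny_subjects()[0, ], tiny_cohort()$measurements[0, ],
               tiny_cohort()$events[0, ])
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_length(paths, 3L)
  for (p in paths) expect_equal(length(readLines(p)), 1L)
})

test_that("invariant violations are rejected with the subject named", {
  mea_bad <- data.frame(subject_id = "A", t_weeks = -5, hba1c = 7)
  expect_error(cohort(tiny_subjects(), mea_bad), "negative measurement time.*A")
  mea_unsorted <- data.frame(subject_id = c("A", "A"), t_weeks = c(10, 5),
                             hba1c = c(7, 7.5))
  expect_error(cohort(tiny_subjects(), mea_unsorted), "not strictly increasing.*A")
  mea_range <- data.frame(subject_id = "B", t_weeks = 0, hba1c = 30)
  expect_error(cohort(tiny_subjects(), mea_range), "HbA1c outside.*B")
  ev_bad <- data.frame(subject_id = "C", L_weeks = 0, R_weeks = 100, t_weeks = 150)
  expect_error(cohort(tiny_subjects(),
                      data.frame(subject_id = "C", t_weeks = 0, hba1c = 8),
                      ev_bad),
               "outside \\(L, R\\].*C")
  expect_error(cohort(tiny_subjects()[, -2],
                      data.frame(subject_id = "A", t_weeks = 0, hba1c = 8)),
               "missing required column.*diagnosis_year")
})

test_that("duplicate measurement times keep the first value with a warning", {
  mea <- data.frame(subject_id = c("A", "A", "A"), t_weeks = c(0, 10, 10),
                    hba1c = c(6.5, 7.0, 9.9))
  expect_warning(co <- cohort(tiny_subjects(), mea), "duplicate")
  expect_equal(co$measurements$hba1c, c(6.5, 7.0))
})

test_that("DDD imputation follows the matching-year rule and is seeded", {
  d <- impute_ddd(2015, 2015, first_hba1c_date = as.Date("2015-06-03"), seed = 99)
  expect_equal(d, as.Date("2015-06-03"))
  d1 <- impute_ddd(2010, 2013, seed = 7)
  d2 <- impute_ddd(2010, 2013, seed = 7)
  expect_identical(d1, d2)
  expect_equal(format(d1, "%Y"), "2010")
})

test_that("imputed DDDs are uniform over the days of the year", {
  days <- vapply(1:10000,
                 function(i) as.integer(format(impute_ddd(2011, 2013, seed = i), "%j")),
                 integer(1))
  expect_true(all(days >= 1 & days <= 365))
  ct <- tabulate(days, 365)
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
})

test_that("leap years draw over 366 days", {
  days <- vapply(1:3000,
                 function(i) as.integer(format(impute_ddd(2012, 2014, seed = i), "%j")),
                 integer(1))
  expect_true(any(days == 366))
})

test_that("observation windows obey the truncation rule", {
  # DDD after the truncation date: window starts at 0
  w <- build_observation_window(as.Date("2015-06-01"), as.Date("2013-01-01"),
                                as.Date("2020-06-01"))
  expect_equal(unname(w[1]), 0)
  expect_gt(w[2], w[1])
  # DDD 520 weeks before truncation, follow-up 884 weeks after DDD
  ddd <- as.Date("2000-01-03")
  w <- build_observation_window(ddd, ddd + 520 * 7, ddd + 884 * 7)
  expect_equal(unname(w), c(520, 884))
  # degenerate: follow-up closes before the window opens
  expect_error(build_observation_window(as.Date("2015-01-01"), as.Date("2014-01-01"),
                                        as.Date("2013-06-01")),
               "after truncation_date|degenerate")
})
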