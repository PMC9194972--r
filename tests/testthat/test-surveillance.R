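test_that("single-fraction flags fire on strict magnitude exceedance only", {
  flags <- flag_type_a(make_records(c(0.5, -11.2, 0.3)))
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$kind, "TYPE_A")
  expect_identical(flags$fractions[[1]], 2L)
  expect_identical(flags$values[[1]], -11.2)

  expect_identical(nrow(flag_type_a(make_records(c(9.9, -9.9, 10.0)))), 0L)
  withr::with_seed(3, safe <- runif(30, -10, 10))
  expect_identical(nrow(flag_type_a(make_records(safe))), 0L)
})

test_that("consecutive-fraction flags cover maximal runs over complete fractions", {
  flags <- flag_type_b(make_records(c(0, 3.5, 3.2, 3.1)))
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$fractions[[1]], 2:4)

  expect_identical(nrow(flag_type_b(make_records(c(0, 3.5, 2.9, 3.5, 3.5)))), 0L)

  # magnitude semantics: signs may differ within a run
  mixed <- flag_type_b(make_records(c(0, 3.5, -3.5, 3.5)))
  expect_identical(nrow(mixed), 1L)
  # unless the same-sign mode is requested
  expect_identical(
    nrow(flag_type_b(make_records(c(0, 3.5, -3.5, 3.5)),
                     flag_config(type_b_same_sign = TRUE))), 0L)

  # one flag per maximal run, all run fractions as triggers
  long_run <- flag_type_b(make_records(c(0, 3.5, 3.5, 3.5, 3.5, 3.5, 0)))
  expect_identical(nrow(long_run), 1L)
  expect_identical(long_run$fractions[[1]], 2:6)
})

test_that("omitted fractions are removed before consecutiveness is evaluated", {
  rec <- make_records(c(0, 3.5, 99, 3.4, 3.3),
                      status = c("complete", "complete", "omitted",
                                 "complete", "complete"))
  flags <- flag_type_b(rec)
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$fractions[[1]], c(2L, 4L, 5L))
  expect_identical(nrow(flag_type_a(rec)), 0L)
})

test_that("daily summaries give the clinic mean and sample SD per treated day", {
  one <- daily_summaries(make_records(0.4))
  expect_identical(one$n_fractions, 1L)
  expect_identical(one$mean_percent, 0.4)
  expect_true(is.na(one$sd_percent))

  rec <- dplyr::bind_rows(make_records(1.0, patient = "A"),
                          make_records(-1.0, patient = "B"))
  two <- daily_summaries(rec)
  expect_identical(two$mean_percent, 0)
  expect_equal(two$sd_percent, sqrt(2), tolerance = 1e-9)

  many <- daily_summaries(dplyr::bind_rows(
    lapply(sprintf("P%02d", 1:20), function(p) make_records(2.0, patient = p))))
  expect_identical(many$mean_percent, 2)
  expect_identical(many$sd_percent, 0)
})

test_that("machine flags compare adjacent treated days, ignoring calendar gaps", {
  summ <- function(dates, means) {
    s <- tibble::tibble(date = as.Date(dates), n_fractions = 10L,
                        mean_percent = means, sd_percent = 0.5)
    class(s) <- c("daily_summaries", class(s))
    s
  }
  f <- machine_output_flags(summ(c("2021-01-04", "2021-01-05"), c(0.1, 1.3)))
  expect_identical(nrow(f), 1L)
  expect_equal(f$difference_percent, 1.2, tolerance = 1e-12)
  expect_identical(f$values[[1]], c(0.1, 1.3))

  expect_identical(nrow(machine_output_flags(
    summ(c("2021-01-04", "2021-01-05", "2021-01-06"), c(0.1, 0.9, 0.2)))), 0L)

  # Friday -> Monday is adjacent in the treated-day sequence
  weekend <- machine_output_flags(summ(c("2021-01-08", "2021-01-11"), c(0.0, 1.6)))
  expect_identical(nrow(weekend), 1L)
  expect_identical(nrow(machine_output_flags(summ("2021-01-04", 5))), 0L)
})

test_that("lowering any threshold never decreases the flag count", {
  withr::with_seed(23, {
    for (k in 1:5) {
      rec <- make_records(c(0, rnorm(14, 0, 4)))
      n_a <- vapply(c(12, 8, 5, 2), function(t) {
        nrow(flag_type_a(rec, flag_config(type_a_threshold_percent = t)))
      }, integer(1))
      expect_true(all(diff(n_a) >= 0))
      n_b <- vapply(c(6, 4, 2, 1), function(t) {
        nrow(flag_type_b(rec, flag_config(type_b_threshold_percent = t)))
      }, integer(1))
      expect_true(all(diff(n_b) >= 0))
    }
  })
})

test_that("with run length 1 and equal thresholds the trend rule reduces to the acute rule", {
  withr::with_seed(29, {
    for (k in 1:5) {
      rec <- make_records(c(0, rnorm(14, 0, 4)))
      cfg <- flag_config(type_a_threshold_percent = 3,
                         type_b_threshold_percent = 3, type_b_run_length = 1)
      a_set <- sort(unlist(flag_type_a(rec, cfg)$fractions))
      b_set <- sort(unlist(flag_type_b(rec, cfg)$fractions))
      expect_identical(a_set, b_set)
    }
  })
})

test_that("report bundles are complete, deterministic and reference-checked", {
  rec <- make_records(c(0, 1, 2, 3.5, 3.2, 3.1, 1, 0.5, -0.5, 0.2))
  flag <- flag_type_b(rec)
  out1 <- withr::local_tempdir()
  dir1 <- build_report(flag, rec, out_dir = out1)
  summary_file <- file.path(dir1, "summary.json")
  expect_true(file.exists(summary_file))
  expect_true(file.exists(file.path(dir1, "trace.png")))
  payload <- jsonlite::read_json(summary_file, simplifyVector = TRUE)
  expect_length(payload$trigger_fractions, 3)
  expect_length(payload$trace$gdsa_percent, 10)

  bytes1 <- readBin(summary_file, "raw", file.size(summary_file))
  out2 <- withr::local_tempdir()
  dir2 <- build_report(flag, rec, out_dir = out2)
  bytes2 <- readBin(file.path(dir2, "summary.json"),
                    "raw", file.size(file.path(dir2, "summary.json")))
  expect_identical(bytes1, bytes2)

  # machine flag report carries both daily means and their difference
  recs <- dplyr::bind_rows(make_records(c(0, 1.4), patient = "A"),
                           make_records(c(0, 1.6), patient = "B"))
  mflag <- machine_output_flags(daily_summaries(recs))
  mdir <- build_report(mflag, recs, out_dir = withr::local_tempdir())
  mp <- jsonlite::read_json(file.path(mdir, "summary.json"), simplifyVector = TRUE)
  expect_identical(mp$values_percent, c(0, 1.5))
  expect_equal(mp$daily_mean_difference_percent, 1.5, tolerance = 1e-9)

  # dangling reference
  dangling <- flag
  dangling$fractions[[1]] <- c(98L, 99L, 100L)
  expect_error(build_report(dangling, rec, out_dir = withr::local_tempdir()),
               class = "epidwatch_consistency_error")
})

test_that("difference panels are emitted when course images are supplied", {
  ph <- phantom_model()
  gc1 <- generate_course(ph, test_config(n_fractions = 4, px = 16),
                         error_injection("TREND", 2, 4, 3))
  rec <- course_gdsa(gc1$series)
  flag <- flag_type_b(rec)
  expect_identical(nrow(flag), 1L)
  dir <- build_report(flag, rec, series = gc1$series,
                      out_dir = withr::local_tempdir())
  expect_length(list.files(dir, pattern = "^difference_fr"), 3)
})
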