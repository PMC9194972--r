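#' One-shot nightly surveillance batch
#'
#' Composes the full pipeline: scan `input_dir` for RTIMAGE files, sort
#' them into courses, compute per-fraction GDSA records, raise flags,
#' compute daily clinic statistics, and write report bundles. Artifacts
#' (`records.csv`, `daily_summaries.csv`, `flags.json`, one report folder
#' per flag) are written deterministically: re-running on unchanged inputs
#' rewrites byte-identical CSV/JSON. Individual unreadable files are
#' logged and skipped; an unreadable input directory is fatal.
#'
#' @param input_dir Directory scanned recursively for portal images.
#' @param out_dir Outbox directory for artifacts and reports.
#' @param params A [roi_params()].
#' @param config A [flag_config()].
#' @param run_date Optional cutoff date: only fractions acquired on or
#'   before it are analyzed (`NULL` = all).
#' @param quiet Suppress stage-count log messages.
#' @return Invisibly, a list with `records`, `summaries`, `flags`,
#'   `report_dirs` and `status` (0 = no flags, 2 = flags raised -- the
#'   machine-readable alert signal).
#' @export
run_nightly <- function(input_dir, out_dir, params = roi_params(),
                        config = flag_config(), run_date = NULL,
                        quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  if (!dir.exists(input_dir)) {
    abort(sprintf("Input directory '%s' is not readable.", input_dir),
          class = "epidwatch_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  images <- scan_rtimages(input_dir)
  log_msg("scan: %d image(s) read from %s", length(images), input_dir)
  if (!is.null(run_date)) {
    run_date <- as.Date(run_date)
    images <- keep(images, function(i) image_date(i) <= run_date)
    log_msg("date filter (<= %s): %d image(s) kept", format(run_date), length(images))
  }
  courses <- sort_images(images)
  log_msg("sort: %d course(s)", length(courses))

  records <- if (length(courses) == 0) analyze_empty_records() else {
    rows <- map(courses, function(cs) {
      tryCatch(course_gdsa(cs, params), error = function(e) {
        warn(sprintf("Skipping course %s/%s: %s", cs$patient_id, cs$plan_id,
                     conditionMessage(e)))
        NULL
      })
    })
    out <- bind_rows(rows)
    if (nrow(out) == 0) analyze_empty_records() else out
  }
  records <- arrange(records, patient_id, plan_id, date, fraction_index)
  log_msg("gdsa: %d record(s), %d omitted", nrow(records),
          sum(records$status == "omitted"))

  summaries <- daily_summaries(records)
  flags <- scan_flags(records, config)
  log_msg("flags: %d (%s)", nrow(flags),
          if (nrow(flags)) paste(flags$kind, collapse = ", ") else "none")

  readr::write_csv(records, file.path(out_dir, "records.csv"))
  readr::write_csv(summaries, file.path(out_dir, "daily_summaries.csv"))
  flags_json <- map(seq_len(nrow(flags)), function(i) {
    f <- flags[i, ]
    list(kind = f$kind, patient_id = f$patient_id, plan_id = f$plan_id,
         trigger_fractions = f$fractions[[1]], trigger_dates = format(f$dates[[1]]),
         values_percent = f$values[[1]],
         difference_percent = f$difference_percent)
  })
  jsonlite::write_json(flags_json, file.path(out_dir, "flags.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")

  report_dirs <- character(0)
  series_index <- setNames(courses, map_chr(courses, function(cs) {
    paste(cs$patient_id, cs$plan_id, sep = "/")
  }))
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    series <- if (f$kind == "MACHINE") NULL else
      series_index[[paste(f$patient_id, f$plan_id, sep = "/")]]
    report_dirs <- c(report_dirs, build_report(f, records, series,
                                               file.path(out_dir, "reports")))
  }

  invisible(list(records = records, summaries = summaries, flags = flags,
                 report_dirs = report_dirs,
                 status = if (nrow(flags) > 0) 2L else 0L))
}

analyze_empty_records <- function() {
  out <- tibble(patient_id = character(), plan_id = character(),
                date = as.Date(character()), fraction_index = integer(),
                gdsa_percent = numeric(), status = character(),
                n_fields = integer(), roi_pixels = numeric())
  class(out) <- c("gdsa_records", class(out))
  out
}
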