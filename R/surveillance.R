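# Three-level surveillance of GDSA records:
#   TYPE_A  -- one fraction beyond +/-10%: acute, large delivery error.
#   TYPE_B  -- `run_length` consecutive fractions beyond +/-3%: systematic
#              trend (weight loss, tumor shrinkage).
#   MACHINE -- clinic-wide daily mean changing by more than 1% between
#              consecutive treated days: output or imager calibration shift.
# "Deviation of +/- X%" is read as strict magnitude exceedance |GDSA| > X;
# boundary equality never flags. Consecutiveness is over complete
# (non-omitted) fractions in date order.

#' Flag thresholds and run lengths
#'
#' @param type_a_threshold_percent Single-fraction magnitude threshold.
#' @param type_b_threshold_percent Consecutive-fraction magnitude threshold.
#' @param type_b_run_length Number of consecutive exceeding fractions.
#' @param machine_threshold_percent Day-to-day daily-mean change threshold.
#' @param type_b_same_sign If `TRUE`, the consecutive deviations must share
#'   a sign (default `FALSE`: magnitude only).
#' @return A `flag_config` object.
#' @export
flag_config <- function(type_a_threshold_percent = 10,
                        type_b_threshold_percent = 3,
                        type_b_run_length = 3L,
                        machine_threshold_percent = 1,
                        type_b_same_sign = FALSE) {
  if (type_a_threshold_percent <= 0 || type_b_threshold_percent <= 0 ||
      machine_threshold_percent <= 0) {
    abort("All thresholds must be > 0.", class = "epidwatch_config_error")
  }
  if (type_b_run_length < 1) {
    abort("`type_b_run_length` must be >= 1.", class = "epidwatch_config_error")
  }
  structure(list(type_a_threshold_percent = type_a_threshold_percent,
                 type_b_threshold_percent = type_b_threshold_percent,
                 type_b_run_length = as.integer(type_b_run_length),
                 machine_threshold_percent = machine_threshold_percent,
                 type_b_same_sign = isTRUE(type_b_same_sign)),
            class = "flag_config")
}

empty_flags <- function() {
  tibble(kind = character(), patient_id = character(), plan_id = character(),
         fractions = list(), dates = list(), values = list(),
         difference_percent = numeric())
}

flag_row <- function(kind, patient_id, plan_id, fractions, dates, values,
                     difference = NA_real_) {
  tibble(kind = kind, patient_id = patient_id, plan_id = plan_id,
         fractions = list(as.integer(fractions)), dates = list(as.Date(dates)),
         values = list(as.numeric(values)), difference_percent = difference)
}

complete_sorted <- function(records) {
  records |> filter(status == "complete") |> arrange(date, fraction_index)
}

#' Single-fraction (Type-A) flags for one course
#'
#' One flag per complete fraction whose GDSA magnitude strictly exceeds the
#' Type-A threshold. Fraction 1 can never flag (its GDSA is 0 by
#' definition).
#'
#' @param records A `gdsa_records` tibble for one course.
#' @param config A [flag_config()].
#' @return A flags tibble (0 or more rows of kind `TYPE_A`).
#' @export
flag_type_a <- function(records, config = flag_config()) {
  rec <- complete_sorted(records)
  hit <- abs(rec$gdsa_percent) > config$type_a_threshold_percent
  if (!any(hit)) return(empty_flags())
  rows <- map(which(hit), function(i) {
    flag_row("TYPE_A", rec$patient_id[i], rec$plan_id[i],
             rec$fraction_index[i], rec$date[i], rec$gdsa_percent[i])
  })
  bind_rows(rows)
}

#' Consecutive-fraction (Type-B) flags for one course
#'
#' Raises one flag per maximal run of at least `type_b_run_length`
#' consecutive complete fractions all strictly exceeding the Type-B
#' threshold in magnitude; all fractions of the run are recorded as
#' triggers. Omitted fractions are removed before consecutiveness is
#' evaluated.
#'
#' @inheritParams flag_type_a
#' @return A flags tibble (0 or more rows of kind `TYPE_B`).
#' @export
flag_type_b <- function(records, config = flag_config()) {
  rec <- complete_sorted(records)
  if (nrow(rec) == 0) return(empty_flags())
  exceed <- abs(rec$gdsa_percent) > config$type_b_threshold_percent
  if (config$type_b_same_sign) {
    # break runs where the deviation sign changes
    sgn <- sign(rec$gdsa_percent)
    brk <- c(FALSE, sgn[-1] != sgn[-length(sgn)])
    run_id <- cumsum(!exceed | brk)
  } else {
    run_id <- cumsum(!exceed)
  }
  rows <- list()
  for (id in unique(run_id[exceed])) {
    idx <- which(exceed & run_id == id)
    if (length(idx) >= config$type_b_run_length) {
      rows[[length(rows) + 1L]] <- flag_row(
        "TYPE_B", rec$patient_id[idx[1]], rec$plan_id[idx[1]],
        rec$fraction_index[idx], rec$date[idx], rec$gdsa_percent[idx])
    }
  }
  if (length(rows) == 0) return(empty_flags())
  bind_rows(rows)
}

#' Daily clinic-wide GDSA statistics
#'
#' For each treatment day, the mean and sample standard deviation (n-1
#' denominator) of the GDSA values of all complete fractions treated that
#' day, across patients. The mean estimates the change in machine output;
#' the SD estimates patient variability. SD is reported as missing when a
#' day holds a single fraction.
#'
#' @param records A `gdsa_records` tibble (all patients).
#' @return A tibble (class `daily_summaries`) with columns `date`,
#'   `n_fractions`, `mean_percent`, `sd_percent`, date-ordered.
#' @export
daily_summaries <- function(records) {
  out <- records |>
    filter(status == "complete") |>
    group_by(date) |>
    summarise(n_fractions = dplyr::n(),
              mean_percent = mean(gdsa_percent),
              sd_percent = ifelse(dplyr::n() > 1, sd(gdsa_percent), NA_real_),
              .groups = "drop") |>
    arrange(date)
  class(out) <- c("daily_summaries", class(out))
  out
}

#' Machine-output flags from consecutive treated days
#'
#' Compares the daily clinic means of adjacent entries of the treated-day
#' sequence (calendar gaps such as weekends are ignored) and flags every
#' pair differing by strictly more than the machine threshold.
#'
#' @param summaries A `daily_summaries` tibble (date-ordered).
#' @param config A [flag_config()].
#' @return A flags tibble (kind `MACHINE`; the two days and their means are
#'   recorded, with the signed difference in `difference_percent`).
#' @export
machine_output_flags <- function(summaries, config = flag_config()) {
  if (nrow(summaries) < 2) return(empty_flags())
  s <- arrange(summaries, date)
  d <- s$mean_percent - lag(s$mean_percent)
  hit <- which(abs(d) > config$machine_threshold_percent)
  if (length(hit) == 0) return(empty_flags())
  rows <- map(hit, function(i) {
    flag_row("MACHINE", NA_character_, NA_character_, integer(0),
             c(s$date[i - 1], s$date[i]),
             c(s$mean_percent[i - 1], s$mean_percent[i]),
             difference = d[i])
  })
  bind_rows(rows)
}

#' All surveillance flags for a set of records
#'
#' Runs the Type-A and Type-B rules per course and the machine rule on the
#' clinic-wide daily means.
#'
#' @param records A `gdsa_records` tibble (all patients).
#' @param config A [flag_config()].
#' @return A flags tibble, ordered by kind, patient and date.
#' @export
scan_flags <- function(records, config = flag_config()) {
  if (nrow(records) == 0) return(empty_flags())
  courses <- records |> distinct(patient_id, plan_id)
  per_course <- purrr::pmap(courses, function(patient_id, plan_id) {
    rec <- records[records$patient_id == patient_id & records$plan_id == plan_id, ]
    bind_rows(flag_type_a(rec, config), flag_type_b(rec, config))
  })
  machine <- machine_output_flags(daily_summaries(records), config)
  out <- bind_rows(bind_rows(per_course), machine)
  out[order(out$kind, out$patient_id, map_chr(out$dates, function(d) format(min(d)))), ]
}

flag_report_name <- function(flag) {
  if (flag$kind == "MACHINE") {
    sprintf("MACHINE_%s", format(max(flag$dates[[1]])))
  } else {
    sprintf("%s_%s_%s_%s", flag$kind, flag$patient_id, flag$plan_id,
            format(min(flag$dates[[1]])))
  }
}

#' Write a report bundle for one flag
#'
#' Produces, in a deterministically named folder under `out_dir`, a
#' machine-readable `summary.json` (flag kind, identity, trigger fractions
#' and values, and the full GDSA trace of the course or the daily-mean
#' sequence) plus a trace plot, and -- when the course images are supplied
#' -- baseline/trigger difference panels. Re-running on identical inputs
#' rewrites a byte-identical `summary.json`.
#'
#' @param flag One row of a flags tibble.
#' @param records The `gdsa_records` the flag was raised from.
#' @param series Optional `course_series` with the images of the flagged
#'   course, for difference panels.
#' @param out_dir Output (outbox) directory.
#' @return The report directory path, invisibly.
#' @export
build_report <- function(flag, records, series = NULL, out_dir = ".") {
  stopifnot(nrow(flag) == 1)
  is_machine <- flag$kind == "MACHINE"
  if (!is_machine) {
    trace <- records |>
      filter(patient_id == flag$patient_id, plan_id == flag$plan_id) |>
      arrange(date, fraction_index)
    if (nrow(trace) == 0 ||
        !all(flag$fractions[[1]] %in% trace$fraction_index[trace$status == "complete"])) {
      abort("Flag references fractions absent from the supplied records.",
            class = "epidwatch_consistency_error")
    }
  }
  dir <- file.path(out_dir, flag_report_name(flag))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  payload <- list(
    kind = flag$kind,
    patient_id = flag$patient_id,
    plan_id = flag$plan_id,
    trigger_fractions = flag$fractions[[1]],
    trigger_dates = format(flag$dates[[1]]),
    values_percent = flag$values[[1]]
  )
  if (is_machine) {
    payload$daily_mean_difference_percent <- flag$difference_percent
    payload$trace <- list(dates = format(flag$dates[[1]]),
                          daily_means_percent = flag$values[[1]])
  } else {
    payload$trace <- list(
      fraction_index = trace$fraction_index,
      date = format(trace$date),
      gdsa_percent = trace$gdsa_percent,
      status = trace$status
    )
  }
  jsonlite::write_json(payload, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")

  plot_obj <- if (is_machine) {
    plot_daily_means(daily_summaries(records))
  } else {
    plot_gdsa_trace(trace)
  }
  save_plot_png(plot_obj, file.path(dir, "trace.png"))

  if (!is_machine && !is.null(series)) {
    baseline <- series$fractions[[1]]
    for (fi in flag$fractions[[1]]) {
      fr <- purrr::detect(series$fractions, function(f) f$fraction_index == fi)
      if (is.null(fr)) next
      save_plot_png(plot_difference_panel(fr$images[[1]], baseline$images[[1]]),
                    file.path(dir, sprintf("difference_fr%02d.png", fi)))
    }
  }
  invisible(dir)
}

save_plot_png <- function(plot, path, width = 7, height = 4.5) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 120, type = "cairo")
  on.exit(grDevices::dev.off())
  print(plot)
}
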