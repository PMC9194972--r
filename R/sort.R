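# Sorting portal images into per-patient, per-plan, date-ordered courses.
# Fraction identity is the calendar date of acquisition: all images a
# patient/plan pair acquired on one date form one treatment fraction.

new_fraction_group <- function(fraction_index, date, images) {
  structure(list(fraction_index = as.integer(fraction_index),
                 date = as.Date(date), images = images),
            class = "fraction_group")
}

new_course_series <- function(patient_id, plan_id, fractions) {
  structure(list(patient_id = patient_id, plan_id = plan_id,
                 fractions = fractions),
            class = "course_series")
}

#' @export
print.course_series <- function(x, ...) {
  cat(sprintf("<course_series> patient %s / plan %s: %d fraction(s), %s .. %s\n",
              x$patient_id, x$plan_id, length(x$fractions),
              format(x$fractions[[1]]$date),
              format(x$fractions[[length(x$fractions)]]$date)))
  invisible(x)
}

group_fields <- function(group) vapply(group$images, function(i) i$field_id, character(1))

#' Sort portal images into treatment courses
#'
#' Groups a flat list of portal images into one course per
#' (patient, plan) pair; within a course, images sharing a calendar
#' acquisition date form one fraction, and fractions are numbered 1..n in
#' date order (fraction 1 is the baseline every later fraction is compared
#' against). Grouping uses image metadata only, never file names, and the
#' result is independent of the input order.
#'
#' @param images List of [epid_image()] objects (may be empty).
#' @return A list of `course_series` objects, ordered by (patient_id,
#'   plan_id).
#' @export
sort_images <- function(images) {
  if (length(images) == 0) return(list())
  index <- tibble(
    patient_id = map_chr(images, "patient_id"),
    plan_id = map_chr(images, "plan_id"),
    field_id = map_chr(images, "field_id"),
    date = as.Date(map_dbl(images, function(i) as.numeric(image_date(i)))),
    i = seq_along(images)
  )
  index <- arrange(index, patient_id, plan_id, date, field_id)
  series_keys <- distinct(index, patient_id, plan_id)
  purrr::pmap(series_keys, function(patient_id, plan_id) {
    rows <- index[index$patient_id == patient_id & index$plan_id == plan_id, ]
    dates <- sort(unique(rows$date))
    fractions <- map(seq_along(dates), function(f) {
      idx <- rows$i[rows$date == dates[f]]
      new_fraction_group(f, dates[f], images[idx])
    })
    new_course_series(patient_id, plan_id, fractions)
  })
}

#' Validate a fraction against the course baseline
#'
#' A fraction is analyzable only when it contains exactly the same set of
#' treatment fields as the first (baseline) fraction: a missing field --
#' typically a beam interruption -- would bias the mean difference high, so
#' such fractions are omitted from all downstream statistics.
#'
#' @param group,baseline `fraction_group` objects from the same course;
#'   `baseline` must be fraction 1.
#' @return `"complete"` or `"omitted"`.
#' @export
validate_fraction <- function(group, baseline) {
  stopifnot(inherits(group, "fraction_group"), inherits(baseline, "fraction_group"))
  same_key <- function(a, b, field) {
    identical(unique(map_chr(a$images, field)), unique(map_chr(b$images, field)))
  }
  if (!same_key(group, baseline, "patient_id") || !same_key(group, baseline, "plan_id")) {
    abort("Fraction and baseline belong to different courses.",
          class = "epidwatch_identity_error")
  }
  gf <- group_fields(group)
  bf <- group_fields(baseline)
  if (anyDuplicated(gf) || anyDuplicated(bf)) {
    abort("Duplicate field_id within a fraction group.",
          class = "epidwatch_identity_error")
  }
  if (setequal(gf, bf)) "complete" else "omitted"
}
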