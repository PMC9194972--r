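# Gradient-dose segmented analysis (GDSA): segment the high-dose,
# low-gradient region of the first-fraction baseline image and summarize
# every later fraction by the mean per-pixel relative difference over that
# region. The region roughly corresponds to the projection of the planning
# target volume onto the imaging panel.

#' Region-of-interest segmentation parameters
#'
#' The baseline is lightly Gaussian-smoothed (to resist hot pixels) before
#' the plateau maximum is taken; the ROI keeps pixels above
#' `dose_threshold_fraction` of that maximum whose local relative gradient
#' (central differences normalized by the local value, converted to %/mm
#' through the pixel pitch) does not exceed `gradient_limit_percent_per_mm`.
#' The defaults (50% dose threshold, 3 %/mm gradient limit, sigma 2 px) are
#' package conventions, configurable here.
#'
#' @param dose_threshold_fraction Fraction of the plateau maximum in (0,1).
#' @param gradient_limit_percent_per_mm Maximum local relative gradient.
#' @param min_roi_pixels Segmentation fails (degenerate field) below this.
#' @param smoothing_sigma_px Gaussian sigma, in pixels, of the light
#'   pre-smoothing.
#' @return A `roi_params` object.
#' @export
roi_params <- function(dose_threshold_fraction = 0.5,
                       gradient_limit_percent_per_mm = 3,
                       min_roi_pixels = 100,
                       smoothing_sigma_px = 2) {
  if (dose_threshold_fraction <= 0 || dose_threshold_fraction >= 1) {
    abort("`dose_threshold_fraction` must be in (0, 1).", class = "epidwatch_config_error")
  }
  if (gradient_limit_percent_per_mm <= 0) {
    abort("`gradient_limit_percent_per_mm` must be > 0.", class = "epidwatch_config_error")
  }
  structure(list(dose_threshold_fraction = dose_threshold_fraction,
                 gradient_limit_percent_per_mm = gradient_limit_percent_per_mm,
                 min_roi_pixels = as.integer(min_roi_pixels),
                 smoothing_sigma_px = smoothing_sigma_px),
            class = "roi_params")
}

# Central-difference relative gradient magnitude in %/mm, evaluated on the
# smoothed image with replicate edges.
relative_gradient <- function(smoothed, pitch_mm) {
  nr <- nrow(smoothed); nc <- ncol(smoothed)
  up    <- smoothed[c(1, seq_len(nr - 1)), , drop = FALSE]
  down  <- smoothed[c(seq_len(nr)[-1], nr), , drop = FALSE]
  left  <- smoothed[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- smoothed[, c(seq_len(nc)[-1], nc), drop = FALSE]
  gy <- (down - up) / (2 * pitch_mm[1])
  gx <- (right - left) / (2 * pitch_mm[2])
  100 * sqrt(gx^2 + gy^2) / pmax(smoothed, .Machine$double.eps)
}

#' Segment the high-dose, low-gradient region of a baseline image
#'
#' @param baseline An [epid_image()] (the first treatment fraction).
#' @param params A [roi_params()].
#' @return An object of class `roi_mask` with fields `mask` (logical matrix)
#'   and `pixel_count`.
#' @export
segment_roi <- function(baseline, params = roi_params()) {
  stopifnot(inherits(baseline, "epid_image"))
  s <- gauss_blur(baseline$pixels, params$smoothing_sigma_px)
  plateau <- max(s)
  high_dose <- s > params$dose_threshold_fraction * plateau
  grad <- relative_gradient(s, pixel_pitch(baseline$geometry))
  mask <- high_dose & (grad <= params$gradient_limit_percent_per_mm)
  count <- sum(mask)
  if (count < params$min_roi_pixels) {
    abort(sprintf("Degenerate field: ROI has %d pixels (< %d required).",
                  count, params$min_roi_pixels),
          class = "epidwatch_degenerate_field_error")
  }
  structure(list(mask = mask, pixel_count = count), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d / %d pixels (%.1f%%)\n", x$pixel_count,
              length(x$mask), 100 * x$pixel_count / length(x$mask)))
  invisible(x)
}

#' GDSA mean difference of a fraction against the baseline
#'
#' Returns `100 * mean((fraction - baseline) / baseline)` over the ROI
#' pixels: the average per-pixel relative difference, in percent, with the
#' baseline always in the denominator.
#'
#' @param fraction,baseline [epid_image()] objects with matching shape.
#' @param roi An `roi_mask` from [segment_roi()].
#' @return Signed percent (scalar).
#' @export
gdsa_mean <- function(fraction, baseline, roi) {
  stopifnot(inherits(fraction, "epid_image"), inherits(baseline, "epid_image"),
            inherits(roi, "roi_mask"))
  if (!identical(dim(fraction$pixels), dim(baseline$pixels)) ||
      !identical(dim(roi$mask), dim(baseline$pixels))) {
    abort("Fraction, baseline and ROI shapes must match.",
          class = "epidwatch_validation_error")
  }
  b <- baseline$pixels[roi$mask]
  if (any(b <= 0)) {
    abort("Baseline has non-positive pixels inside the ROI.",
          class = "epidwatch_division_domain_error")
  }
  f <- fraction$pixels[roi$mask]
  100 * mean((f - b) / b)
}

#' Per-fraction GDSA analysis of a treatment course
#'
#' Segments the ROI once per treatment field on fraction 1 (the ROI is
#' frozen for the whole course), validates every later fraction's field set
#' against the baseline ([validate_fraction()]), and records for each
#' complete fraction the unweighted mean of the per-field GDSA values
#' (fields paired by `field_id`). Fractions with an inconsistent image
#' count -- e.g. a beam interruption -- are marked `omitted` and excluded
#' from all downstream statistics.
#'
#' @param series A `course_series` from [sort_images()] or
#'   [generate_course()].
#' @param params A [roi_params()].
#' @return A tibble (class `gdsa_records`) with columns `patient_id`,
#'   `plan_id`, `date`, `fraction_index`, `gdsa_percent`, `status`,
#'   `n_fields`, `roi_pixels`.
#' @export
course_gdsa <- function(series, params = roi_params()) {
  stopifnot(inherits(series, "course_series"))
  if (length(series$fractions) < 1) {
    abort("Course has no fractions.", class = "epidwatch_course_error")
  }
  baseline <- series$fractions[[1]]
  base_fields <- group_fields(baseline)
  if (anyDuplicated(base_fields)) {
    abort("Baseline fraction has duplicate field_ids.", class = "epidwatch_course_error")
  }
  rois <- tryCatch(
    setNames(map(baseline$images, segment_roi, params = params), base_fields),
    error = function(e) {
      abort(sprintf("Baseline segmentation failed for course %s/%s: %s",
                    series$patient_id, series$plan_id, conditionMessage(e)),
            class = "epidwatch_course_error", parent = e)
    }
  )
  base_by_field <- setNames(baseline$images, base_fields)
  total_roi <- sum(map_dbl(rois, "pixel_count"))

  rows <- map(series$fractions, function(fr) {
    status <- tryCatch(validate_fraction(fr, baseline), error = function(e) {
      warn(sprintf("Fraction %d of %s/%s failed identity validation; marked omitted.",
                   fr$fraction_index, series$patient_id, series$plan_id))
      "omitted"
    })
    g <- NA_real_
    if (status == "complete") {
      fields <- group_fields(fr)
      per_field <- map_dbl(seq_along(fr$images), function(k) {
        fid <- fields[k]
        gdsa_mean(fr$images[[k]], base_by_field[[fid]], rois[[fid]])
      })
      g <- mean(per_field)
    }
    tibble(patient_id = series$patient_id, plan_id = series$plan_id,
           date = fr$date, fraction_index = fr$fraction_index,
           gdsa_percent = g, status = status,
           n_fields = length(fr$images), roi_pixels = total_roi)
  })
  out <- bind_rows(rows)
  class(out) <- c("gdsa_records", class(out))
  out
}

#' Analyze every course found in a directory
#'
#' Scans `input_dir` for RTIMAGE files, sorts them into courses and runs
#' [course_gdsa()] on each; courses whose baseline cannot be segmented are
#' reported and skipped.
#'
#' @param input_dir Directory of RTIMAGE files.
#' @param params A [roi_params()].
#' @return A `gdsa_records` tibble across all courses (possibly empty).
#' @export
analyze_directory <- function(input_dir, params = roi_params()) {
  images <- scan_rtimages(input_dir)
  courses <- sort_images(images)
  rows <- map(courses, function(cs) {
    tryCatch(course_gdsa(cs, params), error = function(e) {
      warn(sprintf("Skipping course %s/%s: %s", cs$patient_id, cs$plan_id,
                   conditionMessage(e)))
      NULL
    })
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(patient_id = character(), plan_id = character(),
                  date = as.Date(character()), fraction_index = integer(),
                  gdsa_percent = numeric(), status = character(),
                  n_fields = integer(), roi_pixels = numeric())
  }
  class(out) <- c("gdsa_records", class(out))
  out
}
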