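# Synthetic transit-image generator.
#
# Physics: first-order exponential attenuation of an open-field fluence
# through a water-equivalent phantom, pixel(x) =
#   open_field_cu * output_scale * exp(-mu * thickness(x))
# with thickness 0 outside the phantom shadow, Gaussian edge blur, and
# multiplicative per-pixel Gaussian noise truncated at zero. No scatter, no
# aperture modulation: the surveillance metric is a *relative change*
# detector, so first-order attenuation reproduces every phenomenon the
# flags must catch (output change, anatomy change, acute error).

#' Phantom model for synthetic transit images
#'
#' An elliptical water-equivalent phantom centered on the beam axis.
#' `shape = "slab"` gives uniform thickness inside the ellipse (a flat
#' transit plateau); `"dome"` gives an ellipsoidal thickness profile. The
#' default semi-axes (300 mm at isocenter) cover the entire 280 x 280 mm
#' panel projection, emulating a treatment field fully covered by anatomy
#' so the whole image is an attenuated plateau.
#'
#' @param semi_axes_mm Ellipse semi-axes `c(row, col)` in mm at the
#'   isocenter plane.
#' @param thickness_cm Water-equivalent thickness in cm (slab value / dome
#'   apex).
#' @param mu_per_cm Linear attenuation coefficient in cm^-1; the default
#'   0.05 approximates water at 6 MV.
#' @param shape `"slab"` or `"dome"`.
#' @return A `phantom_model` object.
#' @export
phantom_model <- function(semi_axes_mm = c(300, 300), thickness_cm = 10,
                          mu_per_cm = 0.05, shape = c("slab", "dome")) {
  shape <- match.arg(shape)
  semi_axes_mm <- rep_len(as.numeric(semi_axes_mm), 2)
  if (any(semi_axes_mm <= 0)) abort("Semi-axes must be positive.", class = "epidwatch_config_error")
  if (thickness_cm < 0) abort("Thickness must be >= 0.", class = "epidwatch_config_error")
  if (mu_per_cm <= 0) abort("`mu_per_cm` must be > 0.", class = "epidwatch_config_error")
  structure(list(semi_axes_mm = semi_axes_mm, thickness_cm = thickness_cm,
                 mu_per_cm = mu_per_cm, shape = shape),
            class = "phantom_model")
}

# Per-pixel water-equivalent path length (cm) projected onto the panel.
thickness_map <- function(phantom, geometry) {
  pit <- iso_pitch(geometry)
  nr <- geometry$matrix_px[1]; nc <- geometry$matrix_px[2]
  y <- (seq_len(nr) - (nr + 1) / 2) * pit[1]
  x <- (seq_len(nc) - (nc + 1) / 2) * pit[2]
  r2 <- outer((y / phantom$semi_axes_mm[1])^2, (x / phantom$semi_axes_mm[2])^2, `+`)
  if (phantom$shape == "slab") {
    ifelse(r2 <= 1, phantom$thickness_cm, 0)
  } else {
    phantom$thickness_cm * sqrt(pmax(0, 1 - r2))
  }
}

#' Configuration of a synthetic treatment course
#'
#' @param n_fractions Number of daily fractions (>= 1), delivered on
#'   consecutive weekdays starting at `start_date`.
#' @param field_ids Treatment field labels; one image per field per
#'   fraction.
#' @param open_field_cu CU level of the unattenuated beam plateau.
#' @param penumbra_sigma_mm Gaussian edge blur in mm at the panel plane.
#' @param noise_sd_percent SD of per-pixel multiplicative Gaussian noise, in
#'   percent of the pixel value (truncated so pixels stay >= 0).
#' @param output_drift_percent_per_fraction Machine output slope: fraction f
#'   is scaled by `(1 + drift/100)^(f-1)`.
#' @param thickness_drift_cm_per_fraction Anatomy change rate in cm per
#'   fraction (negative = weight loss / tumor shrinkage, which *raises* the
#'   transit signal).
#' @param seed Integer seed fixing all randomness of the course.
#' @param start_date First treatment date.
#' @param geometry An [imaging_geometry()].
#' @return A `course_config` object.
#' @export
course_config <- function(n_fractions = 30, field_ids = c("F01", "F02"),
                          open_field_cu = 1.0, penumbra_sigma_mm = 3,
                          noise_sd_percent = 0.5,
                          output_drift_percent_per_fraction = 0,
                          thickness_drift_cm_per_fraction = 0,
                          seed = 1L, start_date = as.Date("2021-01-04"),
                          geometry = imaging_geometry()) {
  if (n_fractions < 1) abort("`n_fractions` must be >= 1.", class = "epidwatch_config_error")
  if (noise_sd_percent < 0) abort("`noise_sd_percent` must be >= 0.", class = "epidwatch_config_error")
  if (open_field_cu <= 0) abort("`open_field_cu` must be > 0.", class = "epidwatch_config_error")
  if (length(field_ids) < 1 || anyDuplicated(field_ids)) {
    abort("`field_ids` must be non-empty and unique.", class = "epidwatch_config_error")
  }
  structure(list(
    n_fractions = as.integer(n_fractions), field_ids = as.character(field_ids),
    open_field_cu = open_field_cu, penumbra_sigma_mm = penumbra_sigma_mm,
    noise_sd_percent = noise_sd_percent,
    output_drift_percent_per_fraction = output_drift_percent_per_fraction,
    thickness_drift_cm_per_fraction = thickness_drift_cm_per_fraction,
    seed = as.integer(seed), start_date = as.Date(start_date),
    geometry = geometry
  ), class = "course_config")
}

#' Injected error scenario
#'
#' `SPIKE` emulates an acute single-fraction delivery error (the target of
#' the 10% single-fraction flag), `TREND` a sustained systematic deviation
#' (the target of the consecutive-fraction flag), and `OUTPUT_STEP` a
#' machine output change shared by a clinic day (the target of the daily
#' machine flag). All three multiply the delivered output by
#' `1 + magnitude_percent/100` for `duration_fractions` fractions starting
#' at `start_fraction`; overlapping `OUTPUT_STEP` injections are rejected
#' as contradictory machine states.
#'
#' @param kind `"SPIKE"`, `"TREND"` or `"OUTPUT_STEP"`.
#' @param start_fraction First affected fraction (1-based).
#' @param magnitude_percent Signed percent change.
#' @param duration_fractions Number of affected fractions (>= 1).
#' @return An `error_injection` object.
#' @export
error_injection <- function(kind = c("SPIKE", "TREND", "OUTPUT_STEP"),
                            start_fraction, magnitude_percent,
                            duration_fractions = 1L) {
  kind <- match.arg(kind)
  if (start_fraction < 1) abort("`start_fraction` must be >= 1.", class = "epidwatch_config_error")
  if (duration_fractions < 1) abort("`duration_fractions` must be >= 1.", class = "epidwatch_config_error")
  structure(list(kind = kind, start_fraction = as.integer(start_fraction),
                 magnitude_percent = magnitude_percent,
                 duration_fractions = as.integer(duration_fractions)),
            class = "error_injection")
}

injection_active <- function(inj, f) {
  f >= inj$start_fraction && f < inj$start_fraction + inj$duration_fractions
}

#' Render one synthetic transit image
#'
#' @param phantom A [phantom_model()].
#' @param config A [course_config()] (supplies CU level, penumbra, noise and
#'   geometry).
#' @param output_scale Machine output ratio applied to the whole image.
#' @param thickness_delta_cm Uniform anatomy change (cm) applied inside the
#'   phantom shadow; must not drive any thickness negative.
#' @param seed Seed for the pixel noise.
#' @param patient_id,plan_id,field_id,acquired Identity metadata for the
#'   emitted image.
#' @return An [epid_image()]; deterministic for a fixed seed.
#' @export
render_transit_image <- function(phantom, config, output_scale = 1,
                                 thickness_delta_cm = 0, seed = config$seed,
                                 patient_id = "SYN001", plan_id = "PLAN1",
                                 field_id = config$field_ids[[1]],
                                 acquired = as.POSIXct(paste(config$start_date, "12:00:00"), tz = "UTC")) {
  geometry <- config$geometry
  tmap <- thickness_map(phantom, geometry)
  inside <- tmap > 0
  if (any(tmap[inside] + thickness_delta_cm < 0)) {
    abort("Thickness delta drives phantom thickness negative.",
          class = "epidwatch_domain_error")
  }
  teff <- tmap
  teff[inside] <- teff[inside] + thickness_delta_cm
  ideal <- config$open_field_cu * output_scale * exp(-phantom$mu_per_cm * teff)
  sigma_px <- config$penumbra_sigma_mm / mean(pixel_pitch(geometry))
  ideal <- gauss_blur(ideal, sigma_px)
  px <- if (config$noise_sd_percent > 0) {
    withr::with_seed(seed, {
      eps <- matrix(rnorm(length(ideal), 0, config$noise_sd_percent / 100),
                    nrow = nrow(ideal))
      ideal * pmax(0, 1 + eps)
    })
  } else {
    ideal
  }
  epid_image(px, patient_id, plan_id, field_id, acquired, geometry)
}

# Consecutive weekdays from `start`, length n.
next_weekdays <- function(start, n) {
  out <- as.Date(character(0))
  d <- as.Date(start)
  while (length(out) < n) {
    if (!(format(d, "%u") %in% c("6", "7"))) out <- c(out, d)
    d <- d + 1
  }
  out
}

# Derive independent sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Core course builder. `extra_scales` (length n_fractions) lets clinic-day
# simulations impose a shared per-day machine output on top of the
# per-course drift and injections; it participates in the expected-GDSA
# closed form.
generate_course_impl <- function(phantom, config, injections, extra_scales,
                                 patient_id, plan_id, dates = NULL) {
  n <- config$n_fractions
  for (inj in injections) {
    if (inj$start_fraction > n) {
      abort("Injection starts beyond the last fraction.", class = "epidwatch_config_error")
    }
  }
  steps <- keep(injections, function(i) i$kind == "OUTPUT_STEP")
  if (length(steps) > 1) {
    for (a in seq_len(length(steps) - 1)) {
      for (b in (a + 1):length(steps)) {
        overlap <- any(vapply(seq_len(n), function(f) {
          injection_active(steps[[a]], f) && injection_active(steps[[b]], f)
        }, logical(1)))
        if (overlap) {
          abort("Overlapping OUTPUT_STEP injections are contradictory.",
                class = "epidwatch_config_error")
        }
      }
    }
  }
  if (is.null(dates)) dates <- next_weekdays(config$start_date, n)
  drift <- config$output_drift_percent_per_fraction
  scales <- vapply(seq_len(n), function(f) {
    s <- (1 + drift / 100)^(f - 1) * extra_scales[f]
    for (inj in injections) {
      if (injection_active(inj, f)) s <- s * (1 + inj$magnitude_percent / 100)
    }
    s
  }, numeric(1))
  deltas <- config$thickness_drift_cm_per_fraction * (seq_len(n) - 1)
  mu <- phantom$mu_per_cm
  expected <- 100 * (scales / scales[1] * exp(-mu * (deltas - deltas[1])) - 1)

  n_fields <- length(config$field_ids)
  seeds <- derive_seeds(config$seed, n * n_fields)
  fractions <- map(seq_len(n), function(f) {
    imgs <- map(seq_len(n_fields), function(k) {
      render_transit_image(
        phantom, config, output_scale = scales[f], thickness_delta_cm = deltas[f],
        seed = seeds[(f - 1) * n_fields + k],
        patient_id = patient_id, plan_id = plan_id,
        field_id = config$field_ids[[k]],
        acquired = as.POSIXct(paste(dates[f], "12:00:00"), tz = "UTC")
      )
    })
    new_fraction_group(f, dates[f], imgs)
  })
  truth <- tibble(
    patient_id = patient_id, plan_id = plan_id,
    fraction_index = seq_len(n), date = dates,
    output_scale = scales, thickness_delta_cm = deltas,
    expected_gdsa_percent = expected
  )
  list(series = new_course_series(patient_id, plan_id, fractions), truth = truth)
}

#' Generate a synthetic treatment course with ground truth
#'
#' Builds a date-ordered course of transit images under the configured
#' output drift, anatomy drift, noise and injected error scenarios, together
#' with a ground-truth log holding each fraction's applied output scale,
#' thickness change, and analytically expected GDSA mean relative to
#' fraction 1:
#' `100 * (scale_f / scale_1 * exp(-mu * delta_f) - 1)` on the attenuated
#' plateau. Fraction 1's expected value is exactly 0 by construction.
#'
#' @inheritParams render_transit_image
#' @param injections List of [error_injection()] objects.
#' @param patient_id,plan_id Identity for the generated course.
#' @return A list with elements `series` (a `course_series`) and `truth`
#'   (a tibble: fraction_index, date, output_scale, thickness_delta_cm,
#'   expected_gdsa_percent).
#' @export
generate_course <- function(phantom, config, injections = list(),
                            patient_id = "SYN001", plan_id = "PLAN1") {
  if (inherits(injections, "error_injection")) injections <- list(injections)
  generate_course_impl(phantom, config, injections,
                       extra_scales = rep(1, config$n_fractions),
                       patient_id = patient_id, plan_id = plan_id)
}

#' Simulate a multi-day clinic
#'
#' Every patient is treated on every date; fraction f of every patient is
#' scaled by the shared machine output `day_output_scales[f]` on top of any
#' per-course drift in `config`. Patient-level noise streams are independent
#' given `seed`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param dates Vector of treatment dates (one fraction per patient per
#'   date).
#' @param day_output_scales Machine output ratio per date (recycled to the
#'   number of dates).
#' @param config A [course_config()]; its `n_fractions` is overridden by
#'   `length(dates)`.
#' @param phantom A [phantom_model()].
#' @param seed Master seed for the whole clinic.
#' @return A list of per-patient lists with elements `series` and `truth`.
#' @export
simulate_clinic <- function(n_patients, dates, day_output_scales = 1,
                            config = course_config(), phantom = phantom_model(),
                            seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be >= 1.", class = "epidwatch_config_error")
  dates <- as.Date(dates)
  scales <- rep_len(day_output_scales, length(dates))
  patient_seeds <- derive_seeds(seed, n_patients)
  map(seq_len(n_patients), function(p) {
    cfg <- config
    cfg$n_fractions <- length(dates)
    cfg$seed <- patient_seeds[p]
    generate_course_impl(phantom, cfg, list(), extra_scales = scales,
                         patient_id = sprintf("SYN%03d", p), plan_id = "PLAN1",
                         dates = dates)
  })
}

#' Generate one clinic day with a shared machine output
#'
#' Each patient receives a two-fraction course fragment: a baseline on the
#' previous weekday at nominal output, and the requested `date` at
#' `day_output_scale`, so the expected GDSA of the day's fraction is
#' `100 * (day_output_scale - 1)` in the noise-free limit.
#'
#' @inheritParams simulate_clinic
#' @param date The clinic day.
#' @param day_output_scale Machine output ratio shared by all patients on
#'   `date`.
#' @return A list of per-patient lists with elements `series` and `truth`.
#' @export
generate_clinic_day <- function(n_patients, date, config = course_config(),
                                day_output_scale = 1, seed = 1L,
                                phantom = phantom_model()) {
  date <- as.Date(date)
  prev <- date - 1
  while (format(prev, "%u") %in% c("6", "7")) prev <- prev - 1
  simulate_clinic(n_patients, dates = c(prev, date),
                  day_output_scales = c(1, day_output_scale),
                  config = config, phantom = phantom, seed = seed)
}

#' Write a synthetic course to a directory
#'
#' Emits one RTIMAGE file per image under
#' `dir/<patient>/<plan>/fr<index>_<field>.dcm` (or `.txt` for the text
#' format), the layout the analysis pipeline scans.
#'
#' @param series A `course_series`.
#' @param dir Output directory (created if needed).
#' @param format Passed to [write_rtimage()].
#' @return Character vector of written paths, invisibly.
#' @export
write_course_series <- function(series, dir, format = c("dicom", "text")) {
  format <- match.arg(format)
  ext <- if (format == "dicom") "dcm" else "txt"
  sub <- file.path(dir, series$patient_id, series$plan_id)
  dir.create(sub, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (fr in series$fractions) {
    for (img in fr$images) {
      p <- file.path(sub, sprintf("fr%02d_%s.%s", fr$fraction_index, img$field_id, ext))
      write_rtimage(img, p, format = format)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write a ground-truth log as CSV
#'
#' @param truth The `truth` tibble from [generate_course()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}
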