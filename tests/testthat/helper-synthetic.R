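# Shared fixture builders. Tests run on a scaled-down imaging geometry
# (same physical panel, coarser matrix) so whole courses render in
# milliseconds; the physics and the analysis are resolution-independent.

test_geometry <- function(px = 48) imaging_geometry(matrix_px = c(px, px))

test_config <- function(n_fractions = 6, noise = 0, px = 48, seed = 1L, ...) {
  course_config(n_fractions = n_fractions, field_ids = "F1",
                noise_sd_percent = noise, penumbra_sigma_mm = 0,
                geometry = test_geometry(px), seed = seed, ...)
}

make_image <- function(pixels, patient = "P1", plan = "PL1", field = "F1",
                       date = "2021-01-04", time = "12:00:00") {
  epid_image(pixels, patient, plan, field,
             as.POSIXct(paste(date, time), tz = "UTC"),
             imaging_geometry(matrix_px = dim(pixels)))
}

uniform_image <- function(value = 1, px = 32, ...) {
  make_image(matrix(value, px, px), ...)
}

full_roi <- function(px) {
  structure(list(mask = matrix(TRUE, px, px), pixel_count = px * px),
            class = "roi_mask")
}

# A gdsa_records tibble built directly from per-fraction values (one
# course, consecutive calendar dates).
make_records <- function(values, status = rep("complete", length(values)),
                         patient = "P1", plan = "PL1",
                         start = as.Date("2021-01-04")) {
  n <- length(values)
  out <- tibble::tibble(
    patient_id = patient, plan_id = plan,
    date = start + seq_len(n) - 1, fraction_index = seq_len(n),
    gdsa_percent = ifelse(status == "omitted", NA_real_, values),
    status = status, n_fields = 1L, roi_pixels = 1000
  )
  class(out) <- c("gdsa_records", class(out))
  out
}
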