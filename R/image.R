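#' Portal (EPID) transit image
#'
#' One megavoltage portal image in calibrated units (CU; 1 CU per monitor
#' unit for a 10 x 10 cm open field) together with the identity metadata the
#' surveillance pipeline sorts on.
#'
#' @param pixels Numeric matrix of pixel values in CU; dimensions must match
#'   `geometry$matrix_px` and all values must be finite and non-negative.
#' @param patient_id,plan_id,field_id Identity strings (medical record
#'   number, plan, and treatment field).
#' @param acquired Acquisition date-time (`POSIXct`, or anything
#'   `as.POSIXct` accepts; interpreted in UTC).
#' @param geometry An [imaging_geometry()].
#'
#' @return An object of class `epid_image`.
#' @export
epid_image <- function(pixels, patient_id, plan_id, field_id, acquired,
                       geometry = imaging_geometry()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "epidwatch_validation_error")
  }
  if (!identical(dim(pixels), as.integer(geometry$matrix_px))) {
    abort(sprintf("Pixel matrix is %d x %d but geometry declares %d x %d.",
                  nrow(pixels), ncol(pixels),
                  geometry$matrix_px[1], geometry$matrix_px[2]),
          class = "epidwatch_validation_error")
  }
  if (any(!is.finite(pixels))) {
    abort("All pixel values must be finite.", class = "epidwatch_validation_error")
  }
  if (any(pixels < 0)) {
    abort("CU pixel values must be >= 0.", class = "epidwatch_validation_error")
  }
  for (f in c("patient_id", "plan_id", "field_id")) {
    v <- get(f)
    if (!is.character(v) || length(v) != 1 || is.na(v) || !nzchar(v)) {
      abort(sprintf("`%s` must be a non-empty string.", f),
            class = "epidwatch_validation_error")
    }
  }
  acquired <- as.POSIXct(acquired, tz = "UTC")
  if (length(acquired) != 1 || is.na(acquired)) {
    abort("`acquired` must be a single valid date-time.",
          class = "epidwatch_validation_error")
  }
  structure(
    list(pixels = pixels, patient_id = patient_id, plan_id = plan_id,
         field_id = field_id, acquired = acquired, geometry = geometry),
    class = "epid_image"
  )
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf(
    "<epid_image> patient %s / plan %s / field %s @ %s\n  %d x %d px, CU range [%.4g, %.4g]\n",
    x$patient_id, x$plan_id, x$field_id,
    format(x$acquired, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# Calendar date of acquisition -- the fraction identity key.
image_date <- function(image) as.Date(image$acquired, tz = "UTC")
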