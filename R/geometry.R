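#' Transit imager geometry
#'
#' Describes the fixed geometry of a megavoltage transit imaging panel.
#' Defaults correspond to the Varian Halcyon aS1200 panel: 154 cm
#' source-to-imager distance, 43 x 43 cm physical panel, 1280 x 1280 pixel
#' matrix, projecting to 28 x 28 cm at isocenter.
#'
#' @param sid_mm Source-to-imager distance in mm.
#' @param panel_mm Physical panel size, `c(height, width)` in mm.
#' @param matrix_px Pixel matrix, `c(rows, cols)`.
#' @param iso_mm Isocentric projection of the panel, `c(height, width)` in mm.
#'
#' @return An object of class `imaging_geometry`.
#' @examples
#' g <- imaging_geometry()
#' pixel_pitch(g)  # mm per pixel at the panel plane
#' @export
imaging_geometry <- function(sid_mm = 1540,
                             panel_mm = c(430, 430),
                             matrix_px = c(1280, 1280),
                             iso_mm = c(280, 280)) {
  panel_mm <- rep_len(as.numeric(panel_mm), 2)
  matrix_px <- rep_len(as.integer(matrix_px), 2)
  iso_mm <- rep_len(as.numeric(iso_mm), 2)
  if (!is.finite(sid_mm) || sid_mm <= 0) {
    abort("`sid_mm` must be a positive length.", class = "epidwatch_geometry_error")
  }
  if (any(!is.finite(panel_mm)) || any(panel_mm <= 0) ||
      any(!is.finite(iso_mm)) || any(iso_mm <= 0)) {
    abort("Panel and isocentric sizes must be strictly positive.",
          class = "epidwatch_geometry_error")
  }
  if (any(is.na(matrix_px)) || any(matrix_px < 2)) {
    abort("Matrix dimensions must be integers >= 2.",
          class = "epidwatch_geometry_error")
  }
  structure(
    list(sid_mm = as.numeric(sid_mm), panel_mm = panel_mm,
         matrix_px = matrix_px, iso_mm = iso_mm),
    class = "imaging_geometry"
  )
}

#' @rdname imaging_geometry
#' @param geometry An `imaging_geometry`.
#' @export
pixel_pitch <- function(geometry) {
  stopifnot(inherits(geometry, "imaging_geometry"))
  geometry$panel_mm / geometry$matrix_px
}

# Pixel pitch at the isocenter plane (mm/px), used to place anatomy that is
# specified in isocentric coordinates.
iso_pitch <- function(geometry) {
  geometry$iso_mm / geometry$matrix_px
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf(
    "<imaging_geometry> SID %.0f mm, panel %.0f x %.0f mm, %d x %d px (%.3f mm pitch)\n",
    x$sid_mm, x$panel_mm[1], x$panel_mm[2], x$matrix_px[1], x$matrix_px[2],
    pixel_pitch(x)[1]
  ))
  invisible(x)
}
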