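# Minimal DICOM RTIMAGE reader/writer (Explicit VR Little Endian only).
# The tag table below is the single source of truth shared by the writer and
# the reader so that synthetic files round-trip bit-exactly.

DICOM_TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_CLASS_RTIMAGE <- "1.2.840.10008.5.1.4.1.1.481.1"
DICOM_IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7432.0.1"
DICOM_UID_ROOT <- "1.2.826.0.1.3680043.9.7432"

# Identity and geometry tag assignments (group, element, VR):
#   patient_id -> (0010,0020) PatientID LO
#   plan_id    -> (0008,103E) SeriesDescription LO
#   field_id   -> (3002,0002) RTImageLabel SH
#   acquired   -> (0008,0022) AcquisitionDate DA + (0008,0032) AcquisitionTime TM
#   SID        -> (3002,0026) RTImageSID DS
DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16_raw <- function(x) {
  x <- as.integer(x)
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2L, endian = "little")
}

u32_raw <- function(x) {
  # avoid 32-bit overflow for lengths >= 2^31 (never needed here, but safe)
  lo <- x %% 65536
  hi <- x %/% 65536
  c(u16_raw(lo), u16_raw(hi))
}

dicom_string_raw <- function(value, pad = c("space", "nul")) {
  pad <- match.arg(pad)
  r <- charToRaw(as.character(value))
  pad_byte <- if (pad == "nul") as.raw(0L) else charToRaw(" ")
  if (length(r) %% 2L == 1L) r <- c(r, pad_byte)
  r
}

dicom_element <- function(group, element, vr, value_raw) {
  stopifnot(length(value_raw) %% 2L == 0L)
  header <- c(u16_raw(group), u16_raw(element), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    c(header, as.raw(c(0, 0)), u32_raw(length(value_raw)), value_raw)
  } else {
    c(header, u16_raw(length(value_raw)), value_raw)
  }
}

dicom_ds <- function(x) {
  # DS values are limited to 16 bytes
  s <- formatC(x, format = "g", digits = 10, width = 1)
  if (nchar(s) > 16) s <- formatC(x, format = "g", digits = 8, width = 1)
  s
}

# Deterministic UID derived from the identity fields (two independent
# polynomial hashes keep distinct identities distinct in practice).
identity_uid <- function(...) {
  bytes <- utf8ToInt(paste(..., sep = "|"))
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 999999937
    h2 <- (h2 * 131 + b) %% 999999893
  }
  paste0(DICOM_UID_ROOT, ".1.", h1, ".", h2)
}

#' Write a portal image as a DICOM RTIMAGE file
#'
#' Emits an Explicit VR Little Endian RTIMAGE file with 16-bit unsigned
#' stored pixels and a per-file rescale slope of `max(CU) / 65535`, which
#' bounds the round-trip quantization error of any pixel by half that slope.
#' With `format = "text"` a language-portable fallback is written instead:
#' the pixel matrix as whitespace-separated text plus a `<path>.json`
#' metadata sidecar.
#'
#' @param image An [epid_image()].
#' @param path Output file path (conventionally `.dcm`, or `.txt` for the
#'   text fallback).
#' @param format `"dicom"` (default) or `"text"`.
#' @return `path`, invisibly.
#' @seealso [read_rtimage()]
#' @export
write_rtimage <- function(image, path, format = c("dicom", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(image, "epid_image"))
  if (format == "text") {
    return(write_rtimage_text(image, path))
  }
  g <- image$geometry
  px <- image$pixels
  max_cu <- max(px)
  slope <- if (max_cu > 0) max_cu / 65535 else 1
  stored <- matrix(as.integer(round(px / slope)), nrow = nrow(px))
  pitch <- pixel_pitch(g)
  sop_uid <- identity_uid(image$patient_id, image$plan_id, image$field_id,
                          format(image$acquired, "%Y%m%d%H%M%S", tz = "UTC"))

  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_element(0x0002, 0x0002, "UI", dicom_string_raw(DICOM_SOP_CLASS_RTIMAGE, "nul")),
    dicom_element(0x0002, 0x0003, "UI", dicom_string_raw(sop_uid, "nul")),
    dicom_element(0x0002, 0x0010, "UI", dicom_string_raw(DICOM_TRANSFER_SYNTAX_EXPLICIT_LE, "nul")),
    dicom_element(0x0002, 0x0012, "UI", dicom_string_raw(DICOM_IMPLEMENTATION_UID, "nul"))
  )
  meta_len <- dicom_element(0x0002, 0x0000, "UL", u32_raw(length(meta)))

  pixel_raw <- u16_raw(as.vector(t(stored)))  # DICOM pixel order is row-major

  dataset <- c(
    dicom_element(0x0008, 0x0016, "UI", dicom_string_raw(DICOM_SOP_CLASS_RTIMAGE, "nul")),
    dicom_element(0x0008, 0x0018, "UI", dicom_string_raw(sop_uid, "nul")),
    dicom_element(0x0008, 0x0022, "DA", dicom_string_raw(format(image$acquired, "%Y%m%d", tz = "UTC"))),
    dicom_element(0x0008, 0x0032, "TM", dicom_string_raw(format(image$acquired, "%H%M%S", tz = "UTC"))),
    dicom_element(0x0008, 0x0060, "CS", dicom_string_raw("RTIMAGE")),
    dicom_element(0x0008, 0x103E, "LO", dicom_string_raw(image$plan_id)),
    dicom_element(0x0010, 0x0020, "LO", dicom_string_raw(image$patient_id)),
    dicom_element(0x0028, 0x0002, "US", u16_raw(1L)),
    dicom_element(0x0028, 0x0004, "CS", dicom_string_raw("MONOCHROME2")),
    dicom_element(0x0028, 0x0010, "US", u16_raw(nrow(px))),
    dicom_element(0x0028, 0x0011, "US", u16_raw(ncol(px))),
    dicom_element(0x0028, 0x0030, "DS", dicom_string_raw(paste0(dicom_ds(pitch[1]), "\\", dicom_ds(pitch[2])))),
    dicom_element(0x0028, 0x0100, "US", u16_raw(16L)),
    dicom_element(0x0028, 0x0101, "US", u16_raw(16L)),
    dicom_element(0x0028, 0x0102, "US", u16_raw(15L)),
    dicom_element(0x0028, 0x0103, "US", u16_raw(0L)),
    dicom_element(0x0028, 0x1052, "DS", dicom_string_raw("0")),
    dicom_element(0x0028, 0x1053, "DS", dicom_string_raw(dicom_ds(slope))),
    dicom_element(0x3002, 0x0002, "SH", dicom_string_raw(image$field_id)),
    dicom_element(0x3002, 0x0026, "DS", dicom_string_raw(dicom_ds(g$sid_mm))),
    dicom_element(0x7FE0, 0x0010, "OW", pixel_raw)
  )

  out <- c(raw(128), charToRaw("DICM"), meta_len, meta, dataset)
  ok <- tryCatch({
    writeBin(out, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort(sprintf("Cannot write RTIMAGE file to '%s'.", path),
          class = "epidwatch_io_error")
  }
  invisible(path)
}

write_rtimage_text <- function(image, path) {
  px <- image$pixels
  lines <- apply(px, 1, function(row) paste(formatC(row, format = "g", digits = 17), collapse = " "))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("Cannot write to '%s'.", path), class = "epidwatch_io_error")
  g <- image$geometry
  meta <- list(
    modality = "RTIMAGE",
    patient_id = image$patient_id,
    plan_id = image$plan_id,
    field_id = image$field_id,
    acquired = format(image$acquired, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    geometry = list(sid_mm = g$sid_mm, panel_mm = g$panel_mm,
                    matrix_px = g$matrix_px, iso_mm = g$iso_mm)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

parse_dicom_elements <- function(bytes, pos) {
  elements <- list()
  n <- length(bytes)
  rd_u16 <- function(at) {
    as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
  }
  while (pos + 7L <= n) {
    group <- rd_u16(pos)
    element <- rd_u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort("Unsupported or corrupt DICOM encoding (expected Explicit VR).",
            class = "epidwatch_parse_error")
    }
    if (vr %in% DICOM_LONG_VRS) {
      len <- rd_u16(pos + 8L) + 65536 * rd_u16(pos + 10L)
      val_start <- pos + 12L
    } else {
      len <- rd_u16(pos + 6L)
      val_start <- pos + 8L
    }
    if (val_start + len - 1L > n) {
      abort("Truncated DICOM element.", class = "epidwatch_parse_error")
    }
    key <- sprintf("%04X%04X", group, element)
    value <- if (len > 0) bytes[val_start:(val_start + len - 1L)] else raw(0)
    elements[[key]] <- list(group = group, element = element, vr = vr, value = value)
    pos <- val_start + len
  }
  elements
}

dicom_str <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  v <- el$value
  # strip trailing space/NUL padding at the byte level
  while (length(v) > 0 && v[length(v)] %in% as.raw(c(0x00, 0x20))) {
    v <- v[-length(v)]
  }
  rawToChar(v)
}

dicom_us <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
}

#' Read a DICOM RTIMAGE portal image
#'
#' Parses an Explicit VR Little Endian DICOM file, checks that its modality
#' is `RTIMAGE`, maps stored pixel values to calibrated units through the
#' file's rescale slope/intercept, and populates identity metadata from the
#' patient, series and beam tags. Files written by [write_rtimage()] with
#' `format = "text"` (matrix + JSON sidecar) are read transparently.
#'
#' @param path Path to the file.
#' @return An [epid_image()].
#' @export
read_rtimage <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "epidwatch_io_error")
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  is_dicom <- length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM"
  if (!is_dicom) {
    if (file.exists(paste0(path, ".json"))) {
      return(read_rtimage_text(path))
    }
    abort(sprintf("'%s' is not a DICOM file (missing DICM magic) and has no metadata sidecar.", path),
          class = "epidwatch_parse_error")
  }
  elements <- parse_dicom_elements(bytes, 133L)
  ts <- dicom_str(elements, "00020010")
  if (!is.null(ts) && ts != DICOM_TRANSFER_SYNTAX_EXPLICIT_LE) {
    abort(sprintf("Unsupported transfer syntax '%s'.", ts),
          class = "epidwatch_parse_error")
  }
  modality <- dicom_str(elements, "00080060")
  if (is.null(modality) || modality != "RTIMAGE") {
    abort(sprintf("Modality is '%s', expected 'RTIMAGE'.",
                  modality %||% "<missing>"),
          class = "epidwatch_modality_error")
  }
  patient_id <- dicom_str(elements, "00100020")
  plan_id <- dicom_str(elements, "0008103E")
  field_id <- dicom_str(elements, "30020002")
  pixel_el <- elements[["7FE00010"]]
  if (is.null(patient_id) || is.null(plan_id) || is.null(field_id) ||
      is.null(pixel_el)) {
    abort("Missing pixel data or identity tags (PatientID, SeriesDescription, RTImageLabel).",
          class = "epidwatch_validation_error")
  }
  rows <- dicom_us(elements, "00280010")
  cols <- dicom_us(elements, "00280011")
  if (is.null(rows) || is.null(cols)) {
    abort("Missing Rows/Columns tags.", class = "epidwatch_validation_error")
  }
  slope_s <- dicom_str(elements, "00281053")
  intercept_s <- dicom_str(elements, "00281052")
  slope <- if (is.null(slope_s)) 1 else as.numeric(slope_s)
  intercept <- if (is.null(intercept_s)) 0 else as.numeric(intercept_s)
  stored <- readBin(pixel_el$value, "integer", n = rows * cols, size = 2,
                    signed = FALSE, endian = "little")
  if (length(stored) < rows * cols) {
    abort("Pixel data shorter than Rows x Columns.", class = "epidwatch_validation_error")
  }
  px <- matrix(stored * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)

  pitch_s <- dicom_str(elements, "00280030")
  sid_s <- dicom_str(elements, "30020026")
  sid <- if (is.null(sid_s)) 1540 else as.numeric(sid_s)
  pitch <- if (is.null(pitch_s)) c(430, 430) / c(rows, cols) else
    as.numeric(strsplit(pitch_s, "\\\\")[[1]])
  panel <- pitch * c(rows, cols)
  geometry <- imaging_geometry(sid_mm = sid, panel_mm = panel,
                               matrix_px = c(rows, cols),
                               iso_mm = panel / (sid / 1000))

  date_s <- dicom_str(elements, "00080022")
  time_s <- dicom_str(elements, "00080032")
  acquired <- as.POSIXct(paste0(date_s %||% "19700101",
                                substr(paste0(time_s %||% "000000", "000000"), 1, 6)),
                         format = "%Y%m%d%H%M%S", tz = "UTC")

  epid_image(px, patient_id, plan_id, field_id, acquired, geometry)
}

read_rtimage_text <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$modality) || meta$modality != "RTIMAGE") {
    abort(sprintf("Modality is '%s', expected 'RTIMAGE'.", meta$modality %||% "<missing>"),
          class = "epidwatch_modality_error")
  }
  vals <- scan(path, what = numeric(), quiet = TRUE)
  gm <- meta$geometry
  geometry <- imaging_geometry(gm$sid_mm, gm$panel_mm, gm$matrix_px, gm$iso_mm)
  rows <- geometry$matrix_px[1]; cols <- geometry$matrix_px[2]
  if (length(vals) != rows * cols) {
    abort("Pixel data does not match the sidecar matrix dimensions.",
          class = "epidwatch_validation_error")
  }
  px <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  epid_image(px, meta$patient_id, meta$plan_id, meta$field_id,
             as.POSIXct(meta$acquired, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
             geometry)
}

#' Scan a directory tree for portal images
#'
#' Recursively reads every `.dcm` / `.txt` file under `input_dir` with
#' [read_rtimage()]. Files that fail to parse or validate are reported with
#' a warning and skipped, so one bad file never aborts a nightly batch.
#'
#' @param input_dir Directory to scan.
#' @return A list of [epid_image()] objects (possibly empty).
#' @export
scan_rtimages <- function(input_dir) {
  if (!dir.exists(input_dir)) {
    abort(sprintf("Input directory '%s' is not readable.", input_dir),
          class = "epidwatch_io_error")
  }
  files <- list.files(input_dir, pattern = "\\.(dcm|txt)$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  files <- sort(files)
  images <- list()
  for (f in files) {
    img <- tryCatch(read_rtimage(f), error = function(e) {
      warn(sprintf("Skipping '%s': %s", f, conditionMessage(e)),
           class = "epidwatch_skipped_file")
      NULL
    })
    if (!is.null(img)) images[[length(images) + 1L]] <- img
  }
  images
}

`%||%` <- function(a, b) if (is.null(a)) b else a
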