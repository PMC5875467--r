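# Minimal DICOM RTIMAGE support.
#
# Only the subset needed to ingest a portal image is handled: explicit-VR
# little-endian transfer syntax, uncompressed 16-bit grayscale pixel data and
# the handful of RT Image tags carrying the acquisition geometry. This is not
# a general DICOM implementation.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

DCM_TAGS <- list(
  modality        = dcm_tag(0x0008, 0x0060),
  content_date    = dcm_tag(0x0008, 0x0023),
  content_time    = dcm_tag(0x0008, 0x0033),
  rows            = dcm_tag(0x0028, 0x0010),
  cols            = dcm_tag(0x0028, 0x0011),
  bits_allocated  = dcm_tag(0x0028, 0x0100),
  machine_name    = dcm_tag(0x3002, 0x0020),
  pixel_spacing   = dcm_tag(0x3002, 0x0011),
  sad             = dcm_tag(0x3002, 0x0022),
  sid             = dcm_tag(0x3002, 0x0026),
  gantry_angle    = dcm_tag(0x300A, 0x011E),
  collimator_angle = dcm_tag(0x300A, 0x0120),
  table_angle     = dcm_tag(0x300A, 0x0122),
  pixel_data      = dcm_tag(0x7FE0, 0x0010)
)

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length.
DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_uint16 <- function(con) readBin(con, "integer", 1L, size = 2L,
                                     endian = "little", signed = FALSE)
read_uint32 <- function(con) {
  lo <- read_uint16(con); hi <- read_uint16(con)
  lo + hi * 65536
}

#' Read a DICOM RT image
#'
#' Reads the subset of a DICOM RTIMAGE file needed for portal-image analysis:
#' gantry, collimator and table angles, imager geometry (SAD, SID, pixel
#' spacing) and the uncompressed 16-bit pixel grid. Only the explicit-VR
#' little-endian transfer syntax is supported.
#'
#' @param path Path to a `.dcm` file.
#' @return A [panel_image()] equivalent to the same acquisition read from the
#'   native TIFF + sidecar dialect.
#' @export
read_dicom_rtimage <- function(path) {
  if (!file.exists(path)) stop("DICOM file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 128L)
  if (rawToChar(readBin(con, "raw", 4L)) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  elems <- list()
  pixel_raw <- NULL
  repeat {
    grp <- readBin(con, "raw", 2L)
    if (length(grp) < 2L) break
    group <- readBin(grp, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
    element <- read_uint16(con)
    vr <- rawToChar(readBin(con, "raw", 2L))
    if (vr %in% DCM_LONG_VRS) {
      readBin(con, "raw", 2L)  # reserved
      len <- read_uint32(con)
    } else {
      len <- read_uint16(con)
    }
    tag <- dcm_tag(group, element)
    payload <- readBin(con, "raw", len)
    if (tag == DCM_TAGS$pixel_data) {
      pixel_raw <- payload
      break
    }
    if (group != 0x0002) elems[[tag]] <- list(vr = vr, raw = payload)
  }
  get_str <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NA_character_)
    trimws(rawToChar(e$raw))
  }
  get_num <- function(tag) suppressWarnings(as.numeric(get_str(tag)))
  get_us <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NA_integer_)
    readBin(e$raw, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  }
  modality <- get_str(DCM_TAGS$modality)
  if (!is.na(modality) && modality != "RTIMAGE")
    stop("unsupported modality '", modality, "' (expected RTIMAGE)", call. = FALSE)
  rows <- get_us(DCM_TAGS$rows); cols <- get_us(DCM_TAGS$cols)
  bits <- get_us(DCM_TAGS$bits_allocated)
  if (is.na(rows) || is.na(cols) || is.null(pixel_raw))
    stop("DICOM file lacks image dimensions or pixel data", call. = FALSE)
  if (!is.na(bits) && bits != 16L)
    stop("only 16-bit pixel data is supported", call. = FALSE)
  spacing <- strsplit(get_str(DCM_TAGS$pixel_spacing), "\\\\")[[1]]
  pitch <- suppressWarnings(as.numeric(spacing[1]))
  sad <- get_num(DCM_TAGS$sad); sid <- get_num(DCM_TAGS$sid)
  if (any(is.na(c(pitch, sad, sid))))
    stop("DICOM file lacks imager geometry tags (3002,0011/0022/0026)", call. = FALSE)
  vals <- readBin(pixel_raw, "integer", rows * cols, size = 2L,
                  endian = "little", signed = FALSE)
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  date <- get_str(DCM_TAGS$content_date); time <- get_str(DCM_TAGS$content_time)
  ts <- if (!is.na(date) && nchar(date) == 8L) {
    sprintf("%s-%s-%sT%sZ", substr(date, 1, 4), substr(date, 5, 6),
            substr(date, 7, 8),
            if (!is.na(time) && nchar(time) >= 6L)
              sprintf("%s:%s:%s", substr(time, 1, 2), substr(time, 3, 4),
                      substr(time, 5, 6)) else "00:00:00")
  } else "1970-01-01T00:00:00Z"
  machine <- get_str(DCM_TAGS$machine_name)
  panel_image(pixels,
              gantry_deg = get_num(DCM_TAGS$gantry_angle),
              collimator_deg = get_num(DCM_TAGS$collimator_angle),
              table_deg = get_num(DCM_TAGS$table_angle),
              geometry = beam_geometry(sad_mm = sad, sid_mm = sid,
                                       pixel_pitch_mm = pitch,
                                       panel_rows = rows, panel_cols = cols),
              machine_id = if (is.na(machine)) "unknown" else machine,
              timestamp = ts)
}

# Internal synthetic DICOM writer used by the test suite to exercise the
# reader; emits the same explicit-VR little-endian subset.
write_dicom_rtimage <- function(image, path, sop_instance_uid = "2.25.1001") {
  stopifnot(inherits(image, "panel_image"))
  pad_even <- function(s, pad = " ") {
    if (nchar(s) %% 2L == 1L) paste0(s, pad) else s
  }
  elem_to_raw <- function(group, element, vr, value) {
    if (vr %in% c("DS", "CS", "LO", "SH", "DA", "TM")) {
      payload <- charToRaw(pad_even(as.character(value)))
    } else if (vr == "UI") {
      payload <- charToRaw(as.character(value))
      if (length(payload) %% 2L == 1L) payload <- c(payload, as.raw(0L))
    } else if (vr == "US") {
      payload <- writeBin(as.integer(value), raw(), size = 2L, endian = "little")
    } else if (vr == "UL") {
      payload <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
    } else if (vr %in% c("OB", "OW")) {
      payload <- value
    } else stop("unsupported VR ", vr)
    head <- c(writeBin(as.integer(c(group, element)), raw(), size = 2L,
                       endian = "little"),
              charToRaw(vr))
    if (vr %in% DCM_LONG_VRS) {
      head <- c(head, as.raw(c(0L, 0L)),
                writeBin(length(payload), raw(), size = 4L, endian = "little"))
    } else {
      head <- c(head, writeBin(length(payload), raw(), size = 2L,
                               endian = "little"))
    }
    c(head, payload)
  }
  dstr <- function(x) format(x, trim = TRUE, scientific = FALSE)
  g <- image$geometry
  # Pixel data: row-major uint16, little endian.
  px <- t(image$pixels)
  pixel_payload <- writeBin(as.integer(as.vector(px)), raw(), size = 2L,
                            endian = "little")
  sop_class <- "1.2.840.10008.5.1.4.1.1.481.1"  # RT Image Storage
  meta_body <- c(elem_to_raw(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
                 elem_to_raw(0x0002, 0x0002, "UI", sop_class),
                 elem_to_raw(0x0002, 0x0003, "UI", sop_instance_uid),
                 elem_to_raw(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(elem_to_raw(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  ts <- image$meta$timestamp
  date8 <- gsub("-", "", substr(ts, 1, 10))
  time6 <- gsub(":", "", substr(ts, 12, 19))
  body <- c(
    elem_to_raw(0x0008, 0x0016, "UI", sop_class),
    elem_to_raw(0x0008, 0x0018, "UI", sop_instance_uid),
    elem_to_raw(0x0008, 0x0023, "DA", date8),
    elem_to_raw(0x0008, 0x0033, "TM", time6),
    elem_to_raw(0x0008, 0x0060, "CS", "RTIMAGE"),
    elem_to_raw(0x0028, 0x0002, "US", 1L),
    elem_to_raw(0x0028, 0x0004, "CS", "MONOCHROME2"),
    elem_to_raw(0x0028, 0x0010, "US", g$panel_rows),
    elem_to_raw(0x0028, 0x0011, "US", g$panel_cols),
    elem_to_raw(0x0028, 0x0100, "US", 16L),
    elem_to_raw(0x0028, 0x0101, "US", 16L),
    elem_to_raw(0x0028, 0x0102, "US", 15L),
    elem_to_raw(0x0028, 0x0103, "US", 0L),
    elem_to_raw(0x3002, 0x0011, "DS",
                paste(dstr(g$pixel_pitch_mm), dstr(g$pixel_pitch_mm), sep = "\\")),
    elem_to_raw(0x3002, 0x0020, "LO", image$meta$machine_id),
    elem_to_raw(0x3002, 0x0022, "DS", dstr(g$sad_mm)),
    elem_to_raw(0x3002, 0x0026, "DS", dstr(g$sid_mm)),
    elem_to_raw(0x300A, 0x011E, "DS", dstr(image$meta$gantry_deg)),
    elem_to_raw(0x300A, 0x0120, "DS", dstr(image$meta$collimator_deg)),
    elem_to_raw(0x300A, 0x0122, "DS", dstr(image$meta$table_deg)),
    elem_to_raw(0x7FE0, 0x0010, "OW", pixel_payload)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
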