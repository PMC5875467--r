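#' Portal image with acquisition metadata
#'
#' Container for a single EPID acquisition: a 16-bit intensity grid plus the
#' machine state it was acquired at.
#'
#' @param pixels Integer matrix (rows x cols), values in `[0, 65535]`.
#' @param gantry_deg,collimator_deg,table_deg Acquisition angles in degrees.
#' @param geometry A [beam_geometry()] whose panel dimensions must match
#'   `dim(pixels)`.
#' @param machine_id Free-text machine identifier.
#' @param timestamp ISO-8601 timestamp string.
#' @param extra Optional named list of additional metadata, preserved through
#'   file round trips but otherwise ignored.
#' @return An object of class `panel_image`.
#' @export
panel_image <- function(pixels, gantry_deg, collimator_deg, table_deg,
                        geometry, machine_id = "virtual",
                        timestamp = "1970-01-01T00:00:00Z", extra = list()) {
  stopifnot(is.matrix(pixels), inherits(geometry, "beam_geometry"))
  if (nrow(pixels) != geometry$panel_rows || ncol(pixels) != geometry$panel_cols)
    stop("pixel grid does not match geometry panel dimensions", call. = FALSE)
  if (!all(is.finite(c(gantry_deg, collimator_deg, table_deg))))
    stop("acquisition angles must be finite", call. = FALSE)
  if (min(pixels) < 0) stop("intensities must be non-negative", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         meta = list(gantry_deg = as.numeric(gantry_deg),
                     collimator_deg = as.numeric(collimator_deg),
                     table_deg = as.numeric(table_deg),
                     machine_id = as.character(machine_id),
                     timestamp = as.character(timestamp),
                     extra = extra),
         geometry = geometry),
    class = "panel_image"
  )
}

#' @export
print.panel_image <- function(x, ...) {
  cat(sprintf("<panel_image> %d x %d px, gantry %g, collimator %g, table %g deg [%s]\n",
              nrow(x$pixels), ncol(x$pixels), x$meta$gantry_deg,
              x$meta$collimator_deg, x$meta$table_deg, x$meta$machine_id))
  invisible(x)
}

sidecar_path <- function(image_path) paste0(tools::file_path_sans_ext(image_path), ".json")

write_panel_image <- function(image, path) {
  stopifnot(inherits(image, "panel_image"))
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  g <- image$geometry
  sidecar <- c(list(gantry_deg = image$meta$gantry_deg,
                    collimator_deg = image$meta$collimator_deg,
                    table_deg = image$meta$table_deg,
                    sad_mm = g$sad_mm, sid_mm = g$sid_mm,
                    pixel_pitch_mm = g$pixel_pitch_mm,
                    panel_rows = g$panel_rows, panel_cols = g$panel_cols,
                    machine_id = image$meta$machine_id,
                    timestamp = image$meta$timestamp),
               image$meta$extra)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

known_sidecar_keys <- c("gantry_deg", "collimator_deg", "table_deg", "sad_mm",
                        "sid_mm", "pixel_pitch_mm", "panel_rows", "panel_cols",
                        "machine_id", "timestamp")

read_panel_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  sc_path <- sidecar_path(path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcm") return(read_dicom_rtimage(path))
  if (!file.exists(sc_path))
    stop("metadata sidecar not found: ", sc_path, call. = FALSE)
  px <- tiff::readTIFF(path)
  if (is.array(px) && length(dim(px)) == 3L) px <- px[, , 1L]
  pixels <- matrix(as.integer(round(px * 65535)), nrow = nrow(px))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (k in known_sidecar_keys)
    if (is.null(sc[[k]])) stop("sidecar missing key '", k, "' for ", path, call. = FALSE)
  geometry <- beam_geometry(sad_mm = sc$sad_mm, sid_mm = sc$sid_mm,
                            pixel_pitch_mm = sc$pixel_pitch_mm,
                            panel_rows = sc$panel_rows, panel_cols = sc$panel_cols)
  panel_image(pixels, gantry_deg = sc$gantry_deg,
              collimator_deg = sc$collimator_deg, table_deg = sc$table_deg,
              geometry = geometry, machine_id = sc$machine_id,
              timestamp = sc$timestamp,
              extra = sc[setdiff(names(sc), known_sidecar_keys)])
}

#' Write an acquisition session to disk
#'
#' Writes one lossless 16-bit grayscale TIFF plus one JSON metadata sidecar
#' per image, and a JSON session manifest listing them in order. The round
#' trip through [read_session()] reproduces pixels bit-exactly.
#'
#' @param images List of [panel_image()] objects.
#' @param directory Output directory (created if needed).
#' @param purpose Either `"isocenter_placement"` (exactly 8 images) or
#'   `"table_rotation"` (at least 3).
#' @param session_id Session identifier written into the manifest.
#' @return The manifest path, invisibly; the manifest itself as attribute.
#' @export
write_session <- function(images, directory, purpose = c("table_rotation", "isocenter_placement"),
                          session_id = format(Sys.time(), "session-%Y%m%d%H%M%S")) {
  purpose <- match.arg(purpose)
  if (length(images) == 0) stop("empty image list", call. = FALSE)
  check_session_count(length(images), purpose)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  tangles <- vapply(images, function(im) im$meta$table_deg, numeric(1))
  dirs <- direction_labels(tangles)
  entries <- vector("list", length(images))
  for (i in seq_along(images)) {
    fname <- sprintf("img_%03d.tif", i)
    write_panel_image(images[[i]], file.path(directory, fname))
    entries[[i]] <- list(file = fname,
                         gantry_deg = images[[i]]$meta$gantry_deg,
                         collimator_deg = images[[i]]$meta$collimator_deg,
                         table_deg = images[[i]]$meta$table_deg,
                         direction = dirs[i])
  }
  manifest <- list(session_id = session_id, purpose = purpose, entries = entries)
  mpath <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(structure(mpath, manifest = manifest))
}

check_session_count <- function(n, purpose) {
  if (purpose == "isocenter_placement" && n != 8L)
    stop("isocenter_placement sessions require exactly 8 images, got ", n,
         call. = FALSE)
  if (purpose == "table_rotation" && n < 3L)
    stop("table_rotation sessions require at least 3 images, got ", n,
         call. = FALSE)
  invisible(n)
}

# Direction of travel per acquisition from the sign of successive table-angle
# differences; repeated angles inherit the preceding label.
direction_labels <- function(table_deg) {
  n <- length(table_deg)
  out <- rep("start", n)
  for (i in seq_len(n)[-1]) {
    d <- table_deg[i] - table_deg[i - 1]
    out[i] <- if (d > 0) "ccw" else if (d < 0) "cw" else out[i - 1]
  }
  out
}

#' Read an acquisition session from a manifest
#'
#' Loads every image listed in a session manifest, in order, cross-checking
#' each file's own metadata against the manifest's expected angles (0.5 deg
#' tolerance) and the image count against the session purpose.
#'
#' @param manifest_path Path to a `manifest.json` written by [write_session()].
#' @return List of [panel_image()] with attributes `purpose`, `session_id` and
#'   `directions`.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$purpose) || is.null(man$entries))
    stop("malformed manifest: ", manifest_path, call. = FALSE)
  entries <- man$entries
  check_session_count(length(entries), man$purpose)
  paths <- vapply(entries, function(e) e$file, character(1))
  if (anyDuplicated(paths)) stop("duplicate image paths in manifest", call. = FALSE)
  base <- dirname(manifest_path)
  images <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    img <- read_panel_image(file.path(base, e$file))
    for (ang in c("gantry_deg", "collimator_deg", "table_deg")) {
      if (!is.null(e[[ang]]) &&
          abs(img$meta[[ang]] - as.numeric(e[[ang]])) > 0.5)
        stop(sprintf("entry %d (%s): %s is %g but manifest expects %g",
                     i, e$file, ang, img$meta[[ang]], as.numeric(e[[ang]])),
             call. = FALSE)
    }
    images[[i]] <- img
  }
  structure(images,
            purpose = man$purpose,
            session_id = man$session_id,
            directions = vapply(entries, function(e)
              if (is.null(e$direction)) "start" else e$direction, character(1)))
}
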