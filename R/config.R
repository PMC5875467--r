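#' Default analysis configuration
#'
#' The full configuration tree with package defaults: `geometry` (SAD, SID,
#' pixel pitch, panel size), `segmentation` (field and BB edge fractions,
#' ray count, BB diameter, radius tolerance), and `analysis` (placement
#' tolerance, caliper resolution, iteration cap, rotation angle sequence,
#' screw constants).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    geometry = list(sad_mm = 1000, sid_mm = 1600, pixel_pitch_mm = 0.4,
                    panel_rows = 1024L, panel_cols = 1024L),
    segmentation = list(field_level_fraction = 0.5, bb_level_fraction = 0.5,
                        n_rays = 64L, bb_diameter_mm = 8,
                        radius_tolerance_frac = 0.10),
    analysis = list(tol_mm = 0.1, caliper_resolution_mm = 0.05, max_iter = 5L,
                    angle_sequence = default_rotation_angles(),
                    k_gt_mm_per_deg = 0.01779, k_ab_mm_per_deg = 0.01843)
  )
}

modify_defaults <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read a YAML configuration file
#'
#' Reads a YAML file with any subset of the [default_config()] keys and
#' merges it over the defaults; unknown keys are preserved.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested named list with helper constructors applied: elements
#'   `geometry_obj`, `segmentation_obj`, `screws_obj` hold the corresponding
#'   S3 objects.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- modify_defaults(cfg, yaml::read_yaml(path))
  }
  cfg$geometry_obj <- do.call(beam_geometry, cfg$geometry)
  cfg$segmentation_obj <- do.call(segmentation_params, cfg$segmentation)
  cfg$screws_obj <- screw_constants(cfg$analysis$k_gt_mm_per_deg,
                                    cfg$analysis$k_ab_mm_per_deg)
  cfg
}
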