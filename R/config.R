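#' Pipeline run configuration
#'
#' Aggregates the constants of the measurement pipeline. The defaults
#' are the published operating points: 0.5 mm^2 collapse threshold,
#' 5 mm^2 near-collapse simplification, 32 radial rays, 2000-point
#' contour, 0.7 s synchronization residual budget, 2 N minimum contact
#' force, 10 cm right-atrium-to-neck distance, and 0.7356 mmHg/cmH2O.
#'
#' @param pixel_pitch Pixel pitch (mm/px); `NA` to take it from the cine.
#' @param collapse_threshold Collapse area threshold (mm^2).
#' @param near_collapse_threshold Area below which segmentation is
#'   region growing only (mm^2).
#' @param n_rays Radial refinement rays.
#' @param n_contour_points Contour interpolation samples.
#' @param sync_residual_max Synchronization residual budget (s).
#' @param min_contact_force Minimum measurable contact force (N).
#' @param ra_to_neck Right atrium to neck base (cm).
#' @param cmh2o_to_mmhg Unit conversion constant.
#' @param rng_seed Seed for any stochastic component.
#' @return A `run_config` list.
#' @export
run_config <- function(pixel_pitch = NA_real_,
                       collapse_threshold = 0.5,
                       near_collapse_threshold = 5,
                       n_rays = 32L,
                       n_contour_points = 2000L,
                       sync_residual_max = 0.7,
                       min_contact_force = 2,
                       ra_to_neck = 10,
                       cmh2o_to_mmhg = 0.7356,
                       rng_seed = 1L) {
  cfg <- list(pixel_pitch = as.numeric(pixel_pitch),
              collapse_threshold = as.numeric(collapse_threshold),
              near_collapse_threshold = as.numeric(near_collapse_threshold),
              n_rays = as.integer(n_rays),
              n_contour_points = as.integer(n_contour_points),
              sync_residual_max = as.numeric(sync_residual_max),
              min_contact_force = as.numeric(min_contact_force),
              ra_to_neck = as.numeric(ra_to_neck),
              cmh2o_to_mmhg = as.numeric(cmh2o_to_mmhg),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$collapse_threshold > 0, cfg$near_collapse_threshold > 0,
            cfg$n_rays >= 4L, cfg$n_contour_points >= 16L,
            cfg$sync_residual_max > 0, cfg$min_contact_force > 0,
            cfg$ra_to_neck > 0, cfg$cmh2o_to_mmhg > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as plain key = value text
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(unclass(config)),
                     vapply(unclass(config), format, character(1),
                            digits = 17)),
             path)
  invisible(path)
}

#' Read a run configuration from key = value text
#' @param path Input path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(
    lapply(kv, function(x) utils::type.convert(x[2], as.is = TRUE)),
    vapply(kv, `[`, character(1), 1))
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

# stable short hash of a config for log provenance
.config_hash <- function(config) {
  s <- paste(names(unclass(config)),
             vapply(unclass(config), format, character(1), digits = 17),
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xFFFFFFFF)
}
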