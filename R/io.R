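# YAML 1.1 parses the bare key `n` (and y/yes/no) as a boolean, which would
# silently mangle the saturation parameter `n`. Repair such keys on read and
# write doubles at full precision so manifests round-trip bit-exactly.
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "FALSE"] <- "n"
    names(x) <- nm
  }
  lapply(x, fix_yaml_keys)
}

read_yaml_cfg <- function(path) fix_yaml_keys(yaml::read_yaml(path))

write_yaml_cfg <- function(x, path) yaml::write_yaml(x, path, precision = 17)

#' Read a simulation run configuration from YAML
#'
#' A run config is a YAML file with sections `grid`, `transport`,
#' `saturation`, `simulation`, and exactly one of `placement` (stochastic
#' geometry) or `mask` (path to a label mask, resolved relative to the
#' config file), plus optional `rois` (list of `roi_id`/`x`/`y`/`radius`),
#' `spheroids` (manual spheroid additions for digitized capsules) and
#' `seed`. Missing keys take the package defaults; every resolved value is
#' echoed in the returned object so a run is reconstructible from its log.
#'
#' @param path YAML file path.
#' @return A `run_config` list with constructed sub-configs.
#' @export
read_run_config <- function(path) {
  raw <- read_yaml_cfg(path)
  schema <- raw$schema %||% "capsim/1"
  if (!identical(schema, "capsim/1")) {
    abort(sprintf("Unsupported config schema '%s'.", schema),
          class = "capsim_schema_error")
  }
  has_mask <- !is.null(raw$mask)
  has_placement <- !is.null(raw$placement)
  if (has_mask && has_placement) {
    abort("Config error at key 'placement'/'mask': supply exactly one of the two.",
          class = "capsim_schema_error")
  }
  if (!has_mask && !has_placement) raw$placement <- list()
  build <- function(ctor, section) {
    known <- names(formals(ctor))
    extra <- setdiff(names(raw[[section]]), known)
    if (length(extra) > 0) {
      abort(sprintf("Config error at key '%s.%s': unknown field.",
                    section, extra[1]),
            class = "capsim_schema_error")
    }
    do.call(ctor, raw[[section]] %||% list())
  }
  cfg <- list(
    schema = schema,
    grid = build(grid_spec, "grid"),
    transport = build(transport_config, "transport"),
    saturation = build(saturation_params, "saturation"),
    simulation = build(simulation_config, "simulation"),
    placement = if (has_placement || !has_mask) build(placement_config, "placement"),
    mask = if (has_mask) file.path(dirname(path), raw$mask),
    spheroids = if (!is.null(raw$spheroids))
      purrr::map_dfr(raw$spheroids, tibble::as_tibble),
    rois = if (!is.null(raw$rois))
      purrr::map_dfr(raw$rois, function(r)
        roi_spec(r$roi_id, r$x, r$y, r$radius)),
    seed = as.integer(raw$seed %||% 1L))
  structure(cfg, class = "run_config")
}

# Build the domain a run config describes (stochastic or digitized).
domain_from_config <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$seed
  if (!is.null(cfg$mask)) {
    dom <- digitize(cfg$mask, cfg$grid, spheroid_spec = cfg$spheroids)
  } else {
    dom <- place_elements(build_domain(cfg$grid), cfg$placement, seed = seed)
  }
  init_diffusivity(dom, cfg$transport)
}

#' Export a capsule domain as plain-text matrices plus a manifest
#'
#' Writes `labels.csv` (integer label matrix), `diffusivity.csv` (when
#' initialized) and `domain.yaml` (geometry manifest: mesh, capsule, seed
#' and the placed-element list).
#'
#' @param domain A `capsule_domain`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
export_domain <- function(domain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(domain$labels, file.path(dir, "labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(domain$diffusivity)) {
    utils::write.table(domain$diffusivity, file.path(dir, "diffusivity.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    nodes_per_side = domain$grid$nodes_per_side,
    side_length_um = domain$grid$side_length,
    capsule_radius_um = domain$grid$capsule_radius,
    capsule_center_um = domain$grid$capsule_center,
    seed = domain$seed,
    elements = if (!is.null(domain$elements))
      purrr::pmap(domain$elements, function(class, x, y, radius, length, angle)
        list(class = class, x = x, y = y, radius = radius,
             length = length, angle = angle)))
  write_yaml_cfg(manifest, file.path(dir, "domain.yaml"))
  invisible(dir)
}

#' Write simulation frames to disk
#'
#' Saves the concentration stack as a multi-page 32-bit float TIFF
#' (`concentration.tif`, one page per frame, ug/mL) plus a frame-time
#' manifest `times.csv` (columns `frame`, `time_min`). Optionally also
#' writes one CSV matrix per frame.
#'
#' @param result A `simulation_result`.
#' @param dir Output directory.
#' @param csv_frames Also write per-frame CSV matrices? (default `FALSE`)
#' @return The directory, invisibly.
#' @export
write_frames <- function(result, dir, csv_frames = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cinj <- result$config$C_inj
  pages <- purrr::map(result$concentration, function(C) {
    t(C)[rev(seq_len(ncol(C))), , drop = FALSE] / cinj
  })
  tiff::writeTIFF(pages, file.path(dir, "concentration.tif"),
                  bits.per.sample = 32L)
  readr::write_csv(tibble(frame = seq_along(result$times) - 1L,
                          time_min = result$times),
                   file.path(dir, "times.csv"))
  if (csv_frames) {
    for (k in seq_along(result$times)) {
      utils::write.table(result$concentration[[k]],
                         file.path(dir, sprintf("frame_%03d.csv", k - 1L)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read and write profile tables
#'
#' Profile CSVs have columns `roi_id`, `time_min`, `value`; ROI definition
#' CSVs have `roi_id`, `center_x_um`, `center_y_um`, `radius_um`.
#'
#' @param path CSV file path.
#' @return `read_profiles()`: a profile tibble; `read_rois()`: a
#'   [roi_spec()] tibble.
#' @export
read_profiles <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("roi_id", "time_min", "value")
  if (!all(need %in% names(p))) {
    abort("Profile CSV must have columns roi_id, time_min, value.",
          class = "capsim_format_error")
  }
  p$roi_id <- as.character(p$roi_id)
  p
}

#' @rdname read_profiles
#' @param profile A profile tibble.
#' @export
write_profiles <- function(profile, path) {
  readr::write_csv(profile[, c("roi_id", "time_min", "value")], path)
  invisible(path)
}

#' @rdname read_profiles
#' @export
read_rois <- function(path) {
  r <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("roi_id", "center_x_um", "center_y_um", "radius_um")
  if (!all(need %in% names(r))) {
    abort("ROI CSV must have columns roi_id, center_x_um, center_y_um, radius_um.",
          class = "capsim_format_error")
  }
  roi_spec(r$roi_id, r$center_x_um, r$center_y_um, r$radius_um)
}
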