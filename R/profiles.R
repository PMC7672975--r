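#' Define circular regions of interest
#'
#' @param id Character ROI identifiers.
#' @param x,y ROI centers in micrometers.
#' @param radius ROI radii in micrometers (> 0).
#' @return A tibble with columns `roi_id`, `x`, `y`, `radius`.
#' @export
roi_spec <- function(id, x, y, radius) {
  if (any(radius <= 0)) {
    abort("ROI radii must be positive.", class = "capsim_config_error")
  }
  tibble(roi_id = as.character(id), x = as.numeric(x), y = as.numeric(y),
         radius = as.numeric(radius))
}

# Linear node indices covered by a circular ROI.
roi_node_index <- function(grid, center, radius) {
  sub <- disc_nodes(grid, center, radius)
  if (nrow(sub) == 0) {
    abort("ROI disc contains no node centers at this mesh resolution.",
          class = "capsim_geometry_error")
  }
  sub[, 1] + (sub[, 2] - 1L) * grid$nodes_per_side
}

#' Extract mean-concentration time profiles for circular ROIs
#'
#' For each frame and each ROI, averages the concentration over all nodes
#' whose centers fall within the ROI disc — the in-silico analogue of the
#' mean fluorescence of a cell cluster section.
#'
#' @param result A `simulation_result`.
#' @param rois A [roi_spec()] tibble (or a single-row list with `x`, `y`,
#'   `radius`).
#' @return A tibble with columns `roi_id`, `time_min`, `value` (ug/mL),
#'   `area` (ROI node count times `dx^2`, um^2) and `normalized = FALSE`.
#' @export
extract_profile <- function(result, rois) {
  stopifnot(inherits(result, "simulation_result"))
  grid <- result$domain$grid
  purrr::pmap_dfr(rois, function(roi_id, x, y, radius, ...) {
    idx <- roi_node_index(grid, c(x, y), radius)
    vals <- vapply(result$concentration, function(C) mean(C[idx]), numeric(1))
    tibble(roi_id = roi_id, time_min = result$times, value = vals,
           area = length(idx) * grid$dx^2, normalized = FALSE)
  })
}

#' Min-max normalize profiles to the unit interval
#'
#' Rescales each ROI profile to span exactly `[0, 1]`, the normalization
#' under which simulated and observed profiles are compared.
#'
#' @param profile A profile tibble (columns `roi_id`, `time_min`, `value`).
#' @return The tibble with `value` rescaled per ROI and `normalized = TRUE`.
#' @export
#' @examples
#' p <- tibble::tibble(roi_id = "a", time_min = 0:2, value = c(2, 7, 12))
#' normalize_profile(p)$value  # 0, 0.5, 1
normalize_profile <- function(profile) {
  out <- profile |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::mutate(.rng = max(.data$value) - min(.data$value))
  if (any(out$.rng <= 0)) {
    bad <- unique(out$roi_id[out$.rng <= 0])
    abort(paste0("Constant profile cannot be normalized: ",
                 paste(bad, collapse = ", ")),
          class = "capsim_degenerate_profile_error")
  }
  out |>
    dplyr::mutate(value = (.data$value - min(.data$value)) / .data$.rng,
                  normalized = TRUE) |>
    dplyr::ungroup() |>
    dplyr::select(-".rng")
}

# Single-ROI accessor with validation.
one_roi <- function(profile) {
  ids <- unique(profile$roi_id)
  if (length(ids) != 1) {
    abort("Expected a single-ROI profile; got multiple roi_id values.",
          class = "capsim_config_error")
  }
  profile[order(profile$time_min), ]
}

#' Delay time of a profile
#'
#' Time at which the profile first exceeds `threshold_frac` of its maximum
#' (its total achieved signal), with linear interpolation between the
#' bracketing frames — a proxy for the time the antibody needs to reach a
#' cluster in detectable amounts. Returns 0 if the profile starts above the
#' threshold, and `NA` (with a warning) if it never crosses it.
#'
#' @param profile A single-ROI profile tibble.
#' @param threshold_frac Fraction of the maximum (default 0.05).
#' @return Delay in minutes.
#' @export
delay_time <- function(profile, threshold_frac = 0.05) {
  p <- one_roi(profile)
  thr <- threshold_frac * max(p$value)
  if (p$value[1] > thr) return(0)
  above <- which(p$value > thr)
  if (length(above) == 0) {
    warn("Profile never exceeds the delay threshold; returning NA.")
    return(NA_real_)
  }
  k <- above[1]
  if (k == 1) return(0)
  # linear interpolation on the bracketing segment
  t0 <- p$time_min[k - 1]; t1 <- p$time_min[k]
  v0 <- p$value[k - 1]; v1 <- p$value[k]
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}

#' Log-phase slope of a profile
#'
#' Ordinary least-squares slope of the profile restricted to its log
#' (growth) phase, defined as the points whose values lie between
#' `band[1]` and `band[2]` of the maximum observed value (default 15-85%).
#'
#' @param profile A single-ROI profile tibble.
#' @param band Length-2 fractions of the maximum delimiting the log phase.
#' @return Slope in signal units per minute.
#' @export
log_phase_slope <- function(profile, band = c(0.15, 0.85)) {
  p <- one_roi(profile)
  mx <- max(p$value)
  sel <- p$value >= band[1] * mx & p$value <= band[2] * mx
  if (sum(sel) < 3) {
    abort("Fewer than 3 points fall inside the log-phase band.",
          class = "capsim_insufficient_data_error")
  }
  unname(coef(lm(value ~ time_min, data = p[sel, ]))[2])
}

#' Summary metrics for every ROI of a profile table
#'
#' @param profile A profile tibble (any number of ROIs).
#' @param threshold_frac,band Passed to [delay_time()] and
#'   [log_phase_slope()].
#' @return One row per ROI: `roi_id`, `area`, `max_value`, `delay_min`,
#'   `slope` (NA where undefined).
#' @export
profile_metrics <- function(profile, threshold_frac = 0.05,
                            band = c(0.15, 0.85)) {
  profile |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(p, key) {
      p$roi_id <- key$roi_id
      slope <- tryCatch(log_phase_slope(p, band), error = function(e) NA_real_)
      delay <- suppressWarnings(delay_time(p, threshold_frac))
      tibble(area = if ("area" %in% names(p)) p$area[1] else NA_real_,
             max_value = max(p$value), delay_min = delay, slope = slope)
    }) |>
    dplyr::ungroup()
}
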