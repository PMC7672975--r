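#' Plot a capsule domain
#'
#' Raster of the node labels with the capsule periphery overlaid.
#'
#' @param object A `capsule_domain`.
#' @param what `"labels"` or `"diffusivity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capsule_domain
#' @export
autoplot.capsule_domain <- function(object, what = c("labels", "diffusivity"),
                                    ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  th <- seq(0, 2 * pi, length.out = 361)
  ring <- tibble(
    x = object$grid$capsule_center[1] + object$grid$capsule_radius * cos(th),
    y = object$grid$capsule_center[2] + object$grid$capsule_radius * sin(th))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  if (what == "labels" || is.null(object$diffusivity)) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$label)) +
      ggplot2::scale_fill_manual(values = c(
        exterior = "grey92", medium = "aliceblue", cancer = "firebrick",
        fibroblast = "seagreen", fiber = "grey20"), drop = FALSE)
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$diffusivity)) +
      ggplot2::scale_fill_viridis_c(name = "D (um^2/s)")
  }
  p + ggplot2::geom_path(data = ring, color = "white", linewidth = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot simulation frames
#'
#' Concentration rasters for a subset of frame times.
#'
#' @param object A `simulation_result`.
#' @param times Frame times (minutes) to show; defaults to 6 evenly spaced
#'   frames.
#' @param ... Unused.
#' @return A ggplot object faceted by frame time.
#' @method autoplot simulation_result
#' @export
autoplot.simulation_result <- function(object, times = NULL, ...) {
  times <- times %||%
    object$times[unique(round(seq(1, length(object$times), length.out = 6)))]
  ax <- node_axis(object$domain$grid)
  df <- purrr::map_dfr(times, function(tm) {
    k <- which.min(abs(object$times - tm))
    C <- object$concentration[[k]]
    tibble(x = rep(ax, times = length(ax)), y = rep(ax, each = length(ax)),
           conc = as.vector(C), time_min = object$times[k])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$conc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "C (ug/mL)") +
    ggplot2::facet_wrap(~time_min, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot ROI profiles
#'
#' @param profile A profile tibble (any number of ROIs).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$time_min, .data$value,
                               color = .data$roi_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "time (min)",
                  y = if (any(profile$normalized)) "normalized signal"
                      else "mean concentration (ug/mL)",
                  color = "ROI")
}

#' Plot a growth-curve fit over its data
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  dense <- tibble(time_min = seq(min(object$data$time_min),
                                 max(object$data$time_min),
                                 length.out = 300))
  dense$value <- predict(object, dense)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_point(size = 0.8, color = "firebrick") +
    ggplot2::geom_line(data = dense, color = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "signal",
                  subtitle = sprintf("%s fit, R^2 = %.4f",
                                     object$family, object$r_squared))
}
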