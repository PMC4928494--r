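#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for gazewalk objects
#'
#' `tidy()` returns the object's contents as a long tibble; `glance()` a
#' one-row summary.
#'
#' @param x a `gw_events`, `behavior_profile` or `sim_result`.
#' @param ... unused.
#' @return a tibble.
#' @name gazewalk-tidiers
NULL

#' @rdname gazewalk-tidiers
#' @method tidy gw_events
#' @export
tidy.gw_events <- function(x, ...) x$events

#' @rdname gazewalk-tidiers
#' @method glance gw_events
#' @export
glance.gw_events <- function(x, ...) {
  ev <- x$events
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_fixations = sum(ev$kind == "fixation"),
    n_saccades = sum(ev$kind == "saccade"),
    mean_fixation_ms = mean(ev$duration_ms[ev$kind == "fixation"]),
    mean_saccade_ms = mean(ev$duration_ms[ev$kind == "saccade"]),
    prop_excluded = mean(x$samples$label == "excluded")
  )
}

#' @rdname gazewalk-tidiers
#' @method tidy behavior_profile
#' @export
tidy.behavior_profile <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(statistic = "fixation_duration", step = NA_integer_,
                   value = x$fixation_durations),
    tibble::tibble(statistic = "saccade_duration", step = NA_integer_,
                   value = x$saccade_durations),
    tibble::tibble(statistic = "departure_angle",
                   step = seq_along(x$departure_angles),
                   value = x$departure_angles),
    tibble::tibble(statistic = "persistence_saccade",
                   step = seq_along(x$persistence_saccade),
                   value = x$persistence_saccade),
    tibble::tibble(statistic = "persistence_fixation",
                   step = seq_along(x$persistence_fixation),
                   value = x$persistence_fixation)
  )
}

#' @rdname gazewalk-tidiers
#' @method glance behavior_profile
#' @export
glance.behavior_profile <- function(x, ...) {
  tibble::tibble(
    n_fixations = x$n_events[["fixation"]],
    n_saccades = x$n_events[["saccade"]],
    median_fixation_ms = x$medians[["fixation_ms"]],
    median_saccade_ms = x$medians[["saccade_ms"]],
    mean_fixation_ms = mean(x$fixation_durations),
    mean_saccade_ms = mean(x$saccade_durations),
    mean_persistence_saccade = mean(x$persistence_saccade),
    mean_persistence_fixation = mean(x$persistence_fixation)
  )
}

#' @rdname gazewalk-tidiers
#' @method tidy sim_result
#' @export
tidy.sim_result <- function(x, ...) x$fixations

#' @rdname gazewalk-tidiers
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_samples = nrow(x$path),
    duration_ms = max(x$path$time_ms),
    n_fixations = nrow(x$fixations),
    n_saccades = sum(x$events$kind == "saccade"),
    seed = x$seed
  )
}

#' Plot methods
#'
#' `autoplot()` methods render maps as rasters (image orientation: y down)
#' and simulated scan paths as a path with fixation marks.
#'
#' @param object a `salience_map`, `fixation_pdf` or `sim_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @name gazewalk-autoplot
NULL

map_to_long <- function(m) {
  tibble::tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)) - 0.5,
    y = rep(seq_len(nrow(m)), times = ncol(m)) - 0.5,
    value = as.numeric(m)
  )
}

#' @rdname gazewalk-autoplot
#' @method autoplot salience_map
#' @export
autoplot.salience_map <- function(object, ...) {
  ggplot2::ggplot(map_to_long(unclass(object)),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "kind")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' @rdname gazewalk-autoplot
#' @method autoplot fixation_pdf
#' @export
autoplot.fixation_pdf <- function(object, ...) {
  ggplot2::ggplot(map_to_long(unclass(object)),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "P(fix)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (dva bins)", y = "y (dva bins)",
                  title = paste("fixation PDF:", attr(object, "source")))
}

#' @rdname gazewalk-autoplot
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, ...) {
  sz <- attr(object$path, "image_size")
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::geom_point(data = object$fixations,
                        ggplot2::aes(size = .data$duration_ms),
                        color = "red", alpha = 0.6) +
    ggplot2::scale_y_reverse(limits = c(sz[1], 0)) +
    ggplot2::scale_x_continuous(limits = c(0, sz[2])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = paste("simulated scan path:", object$model))
}
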