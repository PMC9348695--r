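# Plotting trajectories against measurement tables.

#' Plot a simulated trajectory
#'
#' One panel per observable: blood LDL-C, blood monocytes and lesion area.
#' When a measurement table is supplied, group means are overlaid as points
#' with mean +/- SD error bars; records lying beyond the simulated horizon
#' are an error, and observables absent from the trajectory are skipped
#' with a warning.
#'
#' @param object An `athero_trajectory` from [simulate_model()].
#' @param data Optional measurement table to overlay (a single scenario's
#'   records).
#' @param observables Which observables to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.athero_trajectory <- function(object,
                                       data = NULL,
                                       observables = c("LDL_blood",
                                                       "MONO_blood",
                                                       "lesion_area_pct"),
                                       ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_weeks",
                  dplyr::all_of(observables)),
    cols = -"time_weeks", names_to = "observable", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_weeks,
                                          y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "age [weeks]", y = NULL) +
    ggplot2::theme_minimal()

  if (!is.null(data) && nrow(data) > 0) {
    data <- .validate_measurements(data)
    horizon <- max(object$time_weeks)
    if (any(data$time_weeks > horizon + 1e-9)) {
      stop("measurement records lie beyond the simulated horizon (",
           horizon, " weeks)", call. = FALSE)
    }
    missing <- setdiff(unique(data$observable), observables)
    if (length(missing) > 0) {
      warning("observable(s) not in the trajectory panels, skipped: ",
              paste(missing, collapse = ", "), call. = FALSE)
      data <- data[data$observable %in% observables, , drop = FALSE]
    }
    if (nrow(data) > 0) {
      p <- p +
        ggplot2::geom_pointrange(
          data = data,
          ggplot2::aes(x = .data$time_weeks, y = .data$mean,
                       ymin = .data$mean - .data$sd,
                       ymax = .data$mean + .data$sd),
          colour = "firebrick", linewidth = 0.4, fatten = 2
        )
    }
  }
  p
}

#' Simulate a scenario and plot model against data
#'
#' Convenience wrapper: builds the scenario's input, simulates to the later
#' of `t_end_weeks` and the last record, and renders model curves with the
#' scenario's measurements overlaid.
#'
#' @param params An [athero_params()] object.
#' @param factors An [athero_factors()] object.
#' @param scenario_ An [scenario()] object.
#' @param data Optional measurement table (only this scenario's records are
#'   drawn).
#' @param t_end_weeks Minimal simulated horizon.
#' @param ... Passed to [autoplot.athero_trajectory()].
#' @return A ggplot object.
#' @export
plot_scenario <- function(params, factors, scenario_, data = NULL,
                          t_end_weeks = 28, ...) {
  if (!is.null(data)) {
    data <- .validate_measurements(data)
    data <- data[data$scenario_id == scenario_$id, , drop = FALSE]
    if (nrow(data) > 0) t_end_weeks <- max(t_end_weeks, data$time_weeks)
  }
  tr <- simulate_model(params, scenario_ = scenario_, factors = factors,
                       t_end_weeks = t_end_weeks)
  autoplot.athero_trajectory(tr, data = data, ...)
}
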