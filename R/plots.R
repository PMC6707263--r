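#' Plot methods for trajectories, ensembles and sweeps
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' tibbles: a single trajectory, an ensemble mean with a +/- 2 standard
#' error ribbon, a mean-field curve, and `plot_stationary_sweep()` overlays
#' the stationary-density estimators of a steady-state comparison table
#' against the effective infection rate.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name nmsis-plots
NULL

#' @rdname nmsis-plots
#' @export
autoplot.sis_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$infected)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "infected density I(t)") +
    ggplot2::ylim(0, NA)
}

#' @rdname nmsis-plots
#' @export
autoplot.sis_ensemble <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$infected_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$infected_mean - 2 * .data$infected_se,
      ymax = .data$infected_mean + 2 * .data$infected_se), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "infected density I(t)",
                  subtitle = "ensemble mean ± 2 se") +
    ggplot2::ylim(0, NA)
}

#' @rdname nmsis-plots
#' @export
autoplot.mean_field_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$infected)) +
    ggplot2::geom_line(linetype = 2) +
    ggplot2::labs(x = "time", y = "infected density I(t)",
                  subtitle = "age-structured mean field") +
    ggplot2::ylim(0, NA)
}

#' @rdname nmsis-plots
#' @param comparison A comparison tibble from [run_experiment()] with
#'   columns `lambda_eff`, `estimator`, `mean`, `se`.
#' @export
plot_stationary_sweep <- function(comparison, ...) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$lambda_eff, y = .data$mean,
                               colour = .data$estimator)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 2 * .data$se,
                                          ymax = .data$mean + 2 * .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "effective infection rate", y = "stationary infected density")
}
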