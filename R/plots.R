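#' Plot the per-iteration stereotypy distributions of a report
#'
#' One panel per readout quantity, points and a mean bar per metric.
#'
#' @param object A `stereotypy_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stereotypy_report <- function(object, ...) {
  df <- object$per_iteration
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(
      fun = mean, geom = "crossbar",
      width = 0.4, linewidth = 0.4, colour = "red"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "stereotypy",
      title = sprintf(
        "%s (%d iterations)", object$experiment,
        object$n_iterations
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Stereotypy of the total KC response against the swept value.
#'
#' @param object A `sweep_result` tibble from [run_parameter_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  se <- object$sd_pred_total_kc_response / sqrt(object$n_iterations)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$pred_total_kc_response)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$pred_total_kc_response - se,
      ymax = .data$pred_total_kc_response + se
    )) +
    ggplot2::labs(
      x = unique(object$parameter),
      y = "PRED stereotypy (total KC response)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a convergence x randomness grid as a heatmap
#'
#' @param object A `cr_grid` tibble from [run_convergence_randomness_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cr_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$randomness, y = .data$convergence,
    fill = .data$mean_pred
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "mean PRED") +
    ggplot2::labs(x = "randomness fraction", y = "KC-MBON connection probability") +
    ggplot2::theme_minimal()
}

#' Plot a Hill fit over its data
#'
#' Stereotypy against the convergence:randomness ratio (log axis) with the
#' fitted Hill curve.
#'
#' @param object A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  df <- object$data
  curve <- tibble::tibble(
    r = 10^seq(log10(min(df$r)), log10(max(df$r)), length.out = 200)
  )
  if (!object$degenerate) {
    curve$s <- curve$r^object$a / (object$b + curve$r^object$a)
  } else {
    curve$s <- mean(df$s)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$s)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "black", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "convergence : randomness ratio", y = "stereotypy",
      subtitle = if (object$degenerate) {
        "degenerate fit"
      } else {
        sprintf(
          "S = r^%.2f / (%.2f + r^%.2f), R^2 = %.2f",
          object$a, object$b, object$a, object$r_squared
        )
      }
    ) +
    ggplot2::theme_minimal()
}
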