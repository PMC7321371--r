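#' Plot the optimizer's convergence and collapse history
#'
#' Draws the incumbent best energy and the swarm dispersion percentage per
#' iteration, with the collapse iteration marked. Requires ggplot2.
#'
#' @param result a `pso_result` (or a `prediction_result`, whose
#'   optimization history is used).
#' @param collapse_threshold horizontal reference line for the dispersion
#'   panel, in percent.
#' @return A ggplot object.
#' @export
plot_optimization <- function(result, collapse_threshold = 3) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_optimization requires the ggplot2 package", call. = FALSE)
  if (inherits(result, "prediction_result")) result <- result$optimization
  h <- result$history
  df <- rbind(
    data.frame(iteration = h$iteration, value = h$best_value,
               panel = "best energy"),
    data.frame(iteration = h$iteration, value = h$dispersion_pct,
               panel = "dispersion (%)")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
  if (!is.na(result$collapsed_at))
    p <- p + ggplot2::geom_vline(xintercept = result$collapsed_at,
                                 linetype = "dashed")
  p
}

#' Plot the per-residue deviation profile of a prediction
#'
#' @param result a `prediction_result` evaluated against a native structure.
#' @return A ggplot object.
#' @export
plot_deviation_profile <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_deviation_profile requires the ggplot2 package", call. = FALSE)
  if (is.null(result$evaluation))
    stop("prediction was not evaluated against a native structure",
         call. = FALSE)
  df <- data.frame(residue = seq_along(result$evaluation$per_residue),
                   deviation = result$evaluation$per_residue)
  ggplot2::ggplot(df, ggplot2::aes(x = residue, y = deviation)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "deviation after superposition (Å)")
}
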