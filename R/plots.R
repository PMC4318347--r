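#' Plot a spike raster
#'
#' @param raster A spike tibble (`time`, `neuron`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_raster <- function(raster, ...) {
  ggplot2::ggplot(raster, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.synapse_demo <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("derivative", "theta", "weight"),
                              names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal, levels = c("derivative", "theta", "weight"),
                        labels = c("synaptic derivative", "modification threshold",
                                   "synaptic weight (mV)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$second, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reversal_demo <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$second, y = .data$weight,
                               colour = .data$connection)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "synaptic weight (mV)",
                  colour = "connection") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.isr <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$dt12, y = .data$dt23,
                               fill = .data$active)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "grey92")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "t1 - t2 (ms)", y = "t2 - t3 (ms)", fill = "fires") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.latency_optimization <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("active_default", "active_optimized"),
                        names_to = "variant", values_to = "active") %>%
    mutate(variant = ifelse(.data$variant == "active_default",
                            "non-optimized", "optimized"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dt12, y = .data$dt23,
                                     fill = .data$active)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "grey92")) +
    ggplot2::facet_grid(chain_delay ~ variant) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "t1 - t2 (ms)", y = "t2 - t3 (ms)", fill = "fires") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.png_experiment <- function(object, ...) {
  long <- object$results %>%
    tidyr::pivot_longer(c("png_size", "pruned", "saturated", "other"),
                        names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("png_size", "pruned", "saturated", "other"),
                        labels = c("PNG size", "pruned", "saturated", "non-saturated"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "metaplasticity", y = NULL) +
    ggplot2::theme_minimal()
}
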