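#' Tidy a paired metaplasticity experiment
#'
#' `tidy()` returns the per-network, per-arm measurements; `glance()`
#' aggregates each arm to its mean and appends the paired
#' (enabled - disabled) mean differences.
#'
#' @param x A `png_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.png_experiment <- function(x, ...) {
  x$results
}

#' @rdname tidy.png_experiment
#' @export
glance.png_experiment <- function(x, ...) {
  metrics <- c("png_size", "rate_hz", "pruned", "saturated", "other",
               "active_excitatory", "active_inhibitory", "active_total")
  means <- x$results %>%
    group_by(.data$arm) %>%
    summarise(dplyr::across(dplyr::all_of(metrics), mean), .groups = "drop")
  wide <- x$results %>%
    tidyr::pivot_wider(id_cols = "network", names_from = "arm",
                       values_from = dplyr::all_of(metrics))
  diffs <- tibble(arm = "paired difference")
  for (m in metrics) {
    diffs[[m]] <- mean(wide[[paste0(m, "_enabled")]] - wide[[paste0(m, "_disabled")]])
  }
  bind_rows(means, diffs)
}

#' Summaries of a simulation run
#'
#' `glance()` on a `network_run` reports the spike count, run span and
#' mean per-interval rates.
#'
#' @param x A `network_run` from [run_network()].
#' @param ... Unused.
#' @export
glance.network_run <- function(x, ...) {
  tibble(
    n_spikes = nrow(x$raster),
    t_end_ms = x$network$time,
    mean_rate_excitatory = mean(x$diagnostics$rate_excitatory),
    mean_rate_inhibitory = mean(x$diagnostics$rate_inhibitory),
    mean_theta = mean(x$diagnostics$mean_theta))
}

#' @rdname glance.network_run
#' @export
tidy.network_run <- function(x, ...) {
  x$diagnostics
}
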