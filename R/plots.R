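#' Plot a session's trial-by-trial time series
#'
#' Shows the three observed channels — go RT on go trials, signal-respond
#' RT on failed stops, and the staircasing stop-signal delay — against the
#' trial index.
#'
#' @inheritParams estimate_logan1994
#' @return A ggplot object.
#' @examples
#' plot_session(simulate_session(sst_design(96), seed = 1))
#' @export
plot_session <- function(session) {
  session <- ensure_clusters(session)
  long <- as_tibble(session) |>
    select("trial", "gort_ms", "srrt_ms", "ssd_ms") |>
    tidyr::pivot_longer(-"trial", names_to = "channel", values_to = "ms") |>
    filter(!is.na(.data$ms)) |>
    mutate(channel = factor(.data$channel,
                            levels = c("gort_ms", "srrt_ms", "ssd_ms"),
                            labels = c("GORT", "SRRT", "SSD")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$ms,
                                     colour = .data$channel)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "trial", y = "duration (ms)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a comparison sweep
#'
#' Mean paired differences between the state-space SSRT and each classical
#' index, with 95% confidence intervals, by session length.
#'
#' @param object A tibble from [run_comparison_sweep()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ssrt_sweep
#' @export
autoplot.ssrt_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$n_trials),
                                       y = .data$mean_diff,
                                       colour = .data$pair, group = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.4),
                       alpha = 0.5) +
    ggplot2::labs(x = "trials per session", y = "mean paired difference (ms)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
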