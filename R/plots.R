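#' Plot an injection-cycle trajectory
#'
#' Four stacked panels mirroring the device's dynamic-model figure: piston
#' positions (mm), needle flow (ml/s), cumulative injected volume (ml) and
#' needle force (N), against time since trigger.
#'
#' @param object A `device_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot device_trajectory
#' @export
autoplot.device_trajectory <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(t_s = object$t_s, value = object$x_main_m * 1e3,
           channel = "position (mm)", series = "main piston"),
    tibble(t_s = object$t_s, value = object$x_needle_m * 1e3,
           channel = "position (mm)", series = "needle piston"),
    tibble(t_s = object$t_s, value = object$flow_m3s * 1e6,
           channel = "needle flow (ml/s)", series = "flow"),
    tibble(t_s = object$t_s, value = object$v_injected_ml,
           channel = "injected volume (ml)", series = "volume"),
    tibble(t_s = object$t_s, value = object$force_n,
           channel = "needle force (N)", series = "force")
  )
  df$channel <- factor(df$channel, levels = c(
    "position (mm)", "needle flow (ml/s)", "injected volume (ml)",
    "needle force (N)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time since trigger (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an SpO2 trace
#'
#' Trace with the trigger threshold as a dashed line; optional dose/alert
#' event markers from a controller log.
#'
#' @param object An `spo2_trace`.
#' @param threshold Trigger threshold to mark, percent.
#' @param log Optional controller-log tibble; DOSE events are drawn as
#'   vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spo2_trace
#' @export
autoplot.spo2_trace <- function(object, threshold = 90, log = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s,
                                            y = .data$spo2_pct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "SpO2 (%)") +
    ggplot2::theme_minimal()
  if (!is.null(log) && nrow(log) > 0) {
    doses <- log[log$kind == "DOSE", ]
    if (nrow(doses) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = doses$t_s,
                                   linetype = "dotted")
    }
  }
  p
}

#' Plot a closed-loop run
#'
#' The consumed SpO2 trace with dose events marked.
#'
#' @param object A `closed_loop_result`.
#' @param ... Passed to the trace plot.
#' @return A ggplot object.
#' @method autoplot closed_loop_result
#' @export
autoplot.closed_loop_result <- function(object, ...) {
  autoplot(object$trace, log = object$log, ...)
}
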