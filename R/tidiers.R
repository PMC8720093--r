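#' Tidy an injection-cycle trajectory
#'
#' `tidy()` returns the cycle's phase-transition events; `glance()` a
#' one-row summary of the design milestones: cycle duration, delivered
#' volume, peak needle force, terminal insertion depth, and whether the
#' cycle completed or stalled.
#'
#' @param x A `device_trajectory` from [simulate_cycle()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy device_trajectory
#' @export
tidy.device_trajectory <- function(x, ...) {
  attr(x, "events")
}

#' @rdname tidy.device_trajectory
#' @method glance device_trajectory
#' @export
glance.device_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  fs <- attr(x, "final_state")
  ev <- attr(x, "events")
  done <- ev$t_s[ev$event == "dose_complete"]
  tibble(
    duration_s = if (length(done) > 0) done[1] else utils::tail(x$t_s, 1),
    injected_ml = utils::tail(x$v_injected_ml, 1) - x$v_injected_ml[1],
    peak_force_n = max(x$force_n),
    insertion_depth_mm = insertion_depth(fs, cfg),
    completed = fs$phase == "DONE",
    stalled = isTRUE(attr(x, "stalled"))
  )
}

#' Tidy a closed-loop run
#'
#' `tidy()` returns the controller event log; `glance()` a one-row summary:
#' dose and alert counts, alert time, total volume delivered across
#' trajectories, terminal controller mode and whether any device fault was
#' logged.
#'
#' @param x A `closed_loop_result` from [run_closed_loop()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy closed_loop_result
#' @export
tidy.closed_loop_result <- function(x, ...) {
  x$log
}

#' @rdname tidy.closed_loop_result
#' @method glance closed_loop_result
#' @export
glance.closed_loop_result <- function(x, ...) {
  alerts <- x$log$t_s[x$log$kind == "ALERT"]
  injected <- if (length(x$trajectories) > 0) {
    sum(vapply(x$trajectories,
               function(tr) glance(tr)$injected_ml, numeric(1)))
  } else 0
  tibble(
    n_doses = sum(x$log$kind == "DOSE"),
    n_alerts = length(alerts),
    alert_time_s = if (length(alerts) > 0) alerts[1] else NA_real_,
    total_injected_ml = injected,
    controller_mode = x$final_controller$mode,
    device_fault = any(x$log$kind == "DEVICE_FAULT")
  )
}
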