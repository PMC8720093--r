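#' Initial controller state
#'
#' The dose controller is a small state machine. Modes: `MONITORING`
#' (watching for the trigger), `AWAITING_RECHECK` (dose given, waiting out
#' the redose interval), `RECOVERED` (saturation recovered above threshold
#' at a recheck; the episode is closed and no further dose is given until
#' [reset_controller()]), `EXHAUSTED` (all doses given; sampling continues
#' but no action is taken).
#'
#' @return A `controller_state`.
#' @export
controller_state <- function() {
  structure(
    list(mode = "MONITORING", doses_given = 0L, last_dose_time = NA_real_,
         alert_sent = FALSE, last_t = -Inf, below_count = 0L),
    class = "controller_state"
  )
}

#' Reset the controller for a new wearing episode
#'
#' @param controller A `controller_state`.
#' @return A fresh `controller_state`.
#' @export
reset_controller <- function(controller) {
  controller_state()
}

empty_events <- function() {
  tibble(t_s = numeric(), kind = character(), dose_index = integer(),
         spo2_pct = numeric())
}

#' Advance the controller by one SpO2 sample
#'
#' Trigger rule: while MONITORING, a sample with SpO2 at or below the
#' configured threshold (persisting for `persistence_samples` consecutive
#' samples, default 1) emits the one-per-episode ALERT and DOSE 1
#' simultaneously. While AWAITING_RECHECK, the first sample at or after
#' `last_dose_time + redose_interval` is evaluated: still at or below
#' threshold and doses remain emits the next DOSE; above threshold closes
#' the episode (RECOVERED). After the final dose the controller is
#' EXHAUSTED and takes no further action.
#'
#' @param controller A `controller_state`.
#' @param t Sample time, s; must be non-decreasing across calls.
#' @param spo2 Sample value, percent in \[0, 100\].
#' @param config A `device_config` (threshold, interval, dose count).
#' @return List with `controller` (updated state) and `events` (tibble with
#'   columns `t_s, kind, dose_index, spo2_pct`; zero rows if nothing fired).
#' @export
#' @examples
#' st <- controller_state()
#' controller_step(st, 0, 88, device_config())$events
controller_step <- function(controller, t, spo2, config) {
  if (!is.finite(t) || t < controller$last_t) {
    abort(paste0("out-of-order sample time ", t, " (last ",
                 controller$last_t, ")"),
          class = "odrsim_sequencing_error")
  }
  if (!is.finite(spo2) || spo2 < 0 || spo2 > 100) {
    abort(paste0("SpO2 sample ", spo2, " outside [0, 100]"),
          class = "odrsim_signal_error")
  }
  controller$last_t <- t
  events <- empty_events()
  below <- spo2 <= config$spo2_threshold
  controller$below_count <- if (below) controller$below_count + 1L else 0L

  emit_dose <- function(ctl, ev) {
    ctl$doses_given <- ctl$doses_given + 1L
    ctl$last_dose_time <- t
    if (!ctl$alert_sent) {
      ev <- dplyr::bind_rows(ev, tibble(
        t_s = t, kind = "ALERT", dose_index = NA_integer_, spo2_pct = spo2))
      ctl$alert_sent <- TRUE
    }
    ev <- dplyr::bind_rows(ev, tibble(
      t_s = t, kind = "DOSE", dose_index = ctl$doses_given,
      spo2_pct = spo2))
    ctl$mode <- if (ctl$doses_given >= config$max_doses) "EXHAUSTED" else
      "AWAITING_RECHECK"
    list(ctl = ctl, ev = ev)
  }

  if (controller$mode == "MONITORING") {
    if (below && controller$below_count >= config$persistence_samples) {
      r <- emit_dose(controller, events)
      controller <- r$ctl
      events <- r$ev
    }
  } else if (controller$mode == "AWAITING_RECHECK") {
    if (t >= controller$last_dose_time + config$redose_interval) {
      if (below) {
        r <- emit_dose(controller, events)
        controller <- r$ctl
        events <- r$ev
      } else {
        controller$mode <- "RECOVERED"
      }
    }
  }
  # RECOVERED and EXHAUSTED: keep logging samples, take no action
  list(controller = controller, events = events)
}

#' Run the closed loop: trace in, event log and trajectories out
#'
#' Feeds an SpO2 trace sample-by-sample to the controller. Each DOSE event
#' launches [simulate_cycle()], the first from the READY state and repeat
#' doses continuing from the device's prior terminal state (the needle stays
#' inserted, the fluid piston resumes its travel). A stalled device logs a
#' `DEVICE_FAULT` event and monitoring continues. When the trace carries
#' pharmacokinetic feedback (`pk_feedback` in its scenario parameters), each
#' dose time is fed back into the trace via [apply_dose_response()], so
#' post-dose samples reflect antidote-driven recovery.
#'
#' @param trace An `spo2_trace` tibble (`t_s`, `spo2_pct`), e.g. from
#'   [generate_spo2_trace()] or [read_spo2_csv()].
#' @param config A `device_config`.
#' @param simulate_device Run the mechanical simulation on each dose? With
#'   `FALSE` only the event log is produced.
#' @return A `closed_loop_result` list: `log` (controller-log tibble `t_s,
#'   kind, dose_index, spo2_pct`), `trajectories` (list of
#'   `device_trajectory`, one per attempted dose, each with attribute
#'   `trigger_t`), `final_controller`, `final_device`, `trace` (the trace as
#'   consumed, i.e. after any dose-response feedback).
#' @export
#' @examples
#' cfg <- device_config()
#' tr <- generate_spo2_trace(
#'   scenario_params(overdose_onset = 60, desaturation_rate = 6, floor = 80),
#'   duration = 900, rate = 1, seed = 1)
#' res <- run_closed_loop(tr, cfg, simulate_device = FALSE)
#' res$log
run_closed_loop <- function(trace, config, simulate_device = TRUE) {
  quiet_validate(config)
  if (nrow(trace) == 0) {
    return(structure(
      list(log = empty_events(), trajectories = list(),
           final_controller = controller_state(), final_device = NULL,
           trace = trace),
      class = "closed_loop_result"
    ))
  }
  params <- attr(trace, "params")
  feedback <- !is.null(params) && isTRUE(params$pk_feedback)
  base_trace <- trace
  eff <- trace
  ctl <- controller_state()
  log <- empty_events()
  trajectories <- list()
  device <- NULL
  dose_times <- numeric()
  for (i in seq_len(nrow(trace))) {
    t_i <- eff$t_s[i]
    s_i <- eff$spo2_pct[i]
    r <- controller_step(ctl, t_i, s_i, config)
    ctl <- r$controller
    log <- dplyr::bind_rows(log, r$events)
    if (any(r$events$kind == "DOSE")) {
      dose_times <- c(dose_times, t_i)
      if (simulate_device) {
        init <- if (is.null(device)) device_ready_state(config) else device
        traj <- simulate_cycle(config, initial = init)
        attr(traj, "trigger_t") <- t_i
        trajectories[[length(trajectories) + 1]] <- traj
        device <- attr(traj, "final_state")
        if (isTRUE(attr(traj, "stalled"))) {
          log <- dplyr::bind_rows(log, tibble(
            t_s = t_i, kind = "DEVICE_FAULT", dose_index = NA_integer_,
            spo2_pct = s_i))
        }
      }
      if (feedback) {
        eff <- apply_dose_response(base_trace, dose_times, params)
      }
    }
  }
  if (length(trajectories) > 0) {
    names(trajectories) <- paste0("dose_", seq_along(trajectories))
  }
  structure(
    list(log = log, trajectories = trajectories, final_controller = ctl,
         final_device = device, trace = eff),
    class = "closed_loop_result"
  )
}

#' Screen wearer profiles for device eligibility
#'
#' Eligibility mirrors the clinical entry criteria: no prior or current
#' cardiac or pulmonary disease history, no heart or lung findings on exam,
#' and resting SpO2 of at least 93 percent. Every failed criterion is
#' reported by name.
#'
#' @param profiles A data frame (one row per wearer) with columns
#'   `cardiac_or_pulmonary_history` (logical), `exam_heart_lung_findings`
#'   (logical), `resting_spo2` (percent). A single profile may also be given
#'   as a named list.
#' @param min_resting_spo2 Screening floor, percent.
#' @return A tibble: the input columns plus `eligible` (logical) and
#'   `reasons` (character, `;`-separated failed criteria, `""` if eligible).
#' @export
#' @examples
#' screen_wearer(data.frame(
#'   cardiac_or_pulmonary_history = c(FALSE, FALSE, TRUE),
#'   exam_heart_lung_findings = FALSE,
#'   resting_spo2 = c(96, 92, 97)))
screen_wearer <- function(profiles, min_resting_spo2 = 93) {
  if (!is.data.frame(profiles)) profiles <- as_tibble(as.list(profiles))
  need <- c("cardiac_or_pulmonary_history", "exam_heart_lung_findings",
            "resting_spo2")
  missing_f <- setdiff(need, names(profiles))
  if (length(missing_f) > 0) {
    abort(paste0("profile missing field(s): ",
                 paste(missing_f, collapse = ", ")),
          class = "odrsim_profile_error")
  }
  if (any(is.na(profiles[need]))) {
    abort("profile fields must not contain missing values",
          class = "odrsim_profile_error")
  }
  profiles <- as_tibble(profiles)
  reasons <- purrr::pmap_chr(
    profiles[need],
    function(cardiac_or_pulmonary_history, exam_heart_lung_findings,
             resting_spo2) {
      r <- character()
      if (cardiac_or_pulmonary_history) {
        r <- c(r, "cardiac or pulmonary disease history")
      }
      if (exam_heart_lung_findings) {
        r <- c(r, "heart or lung disease on exam")
      }
      if (resting_spo2 < min_resting_spo2) {
        r <- c(r, paste0("resting SpO2 < ", min_resting_spo2, "%"))
      }
      paste(r, collapse = "; ")
    }
  )
  dplyr::mutate(profiles, eligible = reasons == "", reasons = reasons)
}

#' @export
print.closed_loop_result <- function(x, ...) {
  nd <- sum(x$log$kind == "DOSE")
  na <- sum(x$log$kind == "ALERT")
  cat(sprintf("<closed_loop_result> %d dose(s), %d alert(s), mode %s\n",
              nd, na, x$final_controller$mode))
  if (nrow(x$log) > 0) print(x$log)
  invisible(x)
}
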