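fmt12 <- function(x) sprintf("%.12g", x)

#' Load device and scenario configuration from YAML or JSON
#'
#' A configuration file holds a `device:` section (keys exactly the
#' [device_config()] argument names) and an optional `scenario:` section
#' (keys the [scenario_params()] argument names). A file without either
#' section is treated as a bare device map. Unknown keys are rejected with
#' the offending key named. Parse errors, validation errors and unknown-key
#' errors carry distinct condition classes.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `device` (a `device_config`) and `scenario`
#'   (a `scenario_params`, or `NULL` if the file has no scenario section).
#' @export
#' @examples
#' path <- system.file("extdata", "default.yaml", package = "odrsim")
#' cfg <- load_config(path)$device
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "odrsim_parse_error")
  }
  raw <- tryCatch(
    {
      if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(path)
      }
    },
    error = function(e) {
      abort(paste0("cannot parse config file ", path, ": ",
                   conditionMessage(e)),
            class = "odrsim_parse_error")
    }
  )
  if (!is.list(raw)) {
    abort("config file must contain a key-value mapping",
          class = "odrsim_parse_error")
  }
  if (!any(c("device", "scenario") %in% names(raw))) {
    raw <- list(device = raw)
  }
  extra_top <- setdiff(names(raw), c("device", "scenario"))
  if (length(extra_top) > 0) {
    abort(paste0("unknown top-level config key: '", extra_top[1], "'"),
          class = "odrsim_unknown_key_error")
  }
  dev_args <- raw$device %||% list()
  known <- names(formals(device_config))
  unknown <- setdiff(names(dev_args), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown device config key: '", unknown[1], "'"),
          class = "odrsim_unknown_key_error")
  }
  device <- do.call(device_config, dev_args)
  scenario <- NULL
  if (!is.null(raw$scenario)) {
    known_s <- names(formals(scenario_params))
    unknown_s <- setdiff(names(raw$scenario), known_s)
    if (length(unknown_s) > 0) {
      abort(paste0("unknown scenario config key: '", unknown_s[1], "'"),
            class = "odrsim_unknown_key_error")
    }
    scenario <- do.call(scenario_params, raw$scenario)
  }
  list(device = device, scenario = scenario)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an SpO2 trace as CSV
#'
#' Plain CSV with columns `t_s,spo2_pct`, values formatted `%.12g` for exact
#' round-trips, preceded by a `# seed=` comment header recording the trace's
#' RNG seed.
#'
#' @param trace An `spo2_trace`.
#' @param path Output path.
#' @return `path`, invisibly (writer); an `spo2_trace` (reader).
#' @export
write_spo2_csv <- function(trace, path) {
  seed <- attr(trace, "seed")
  lines <- c(
    paste0("# seed=", if (is.null(seed)) "NA" else seed),
    "t_s,spo2_pct",
    paste(fmt12(trace$t_s), fmt12(trace$spo2_pct), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spo2_csv
#' @export
read_spo2_csv <- function(path) {
  lines <- readLines(path)
  seed <- NULL
  header <- grepl("^#", lines)
  sline <- lines[header][grepl("seed=", lines[header])]
  if (length(sline) > 0) {
    s <- sub(".*seed=", "", sline[1])
    if (s != "NA") seed <- as.integer(s)
  }
  df <- utils::read.csv(text = lines[!header])
  structure(
    as_tibble(df),
    class = c("spo2_trace", class(tibble())),
    seed = seed,
    params = NULL
  )
}

traj_cols <- c("t_s", "x_main_m", "v_main_ms", "x_needle_m", "v_needle_ms",
               "p_lower_pa", "p_fluid_pa", "flow_m3s", "v_injected_ml",
               "force_n", "phase")

#' Write / read a device trajectory as CSV
#'
#' Exports the per-millisecond trajectory channels with the fixed header
#' `t_s,x_main_m,v_main_ms,x_needle_m,v_needle_ms,p_lower_pa,p_fluid_pa,`
#' `flow_m3s,v_injected_ml,force_n,phase`; numbers formatted `%.12g`.
#'
#' @param traj A `device_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)[traj_cols]
  num <- vapply(df, is.numeric, logical(1))
  body <- do.call(paste, c(lapply(seq_along(df), function(i) {
    if (num[i]) fmt12(df[[i]]) else df[[i]]
  }), sep = ","))
  writeLines(c(paste(traj_cols, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  as_tibble(utils::read.csv(path, colClasses = c(phase = "character")))
}

#' Write / read a controller event log as JSON Lines
#'
#' One JSON object per line with fields `t_s`, `kind`, `dose_index`,
#' `spo2_pct`; ALERT events carry a placeholder `gps: null` field (alert
#' transport is modeled as a logged event only).
#'
#' @param log Controller-log tibble (`t_s, kind, dose_index, spo2_pct`).
#' @param path Output path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_events_jsonl <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    rec <- list(
      t_s = log$t_s[i],
      kind = log$kind[i],
      dose_index = if (is.na(log$dose_index[i])) NULL else log$dose_index[i],
      spo2_pct = log$spo2_pct[i]
    )
    if (log$kind[i] == "ALERT") rec$gps <- NA
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null",
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_events())
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
  tibble(
    t_s = vapply(recs, function(r) as.numeric(r$t_s), numeric(1)),
    kind = vapply(recs, function(r) as.character(r$kind), character(1)),
    dose_index = vapply(recs, function(r) {
      if (is.null(r$dose_index) || is.na(r$dose_index)) NA_integer_
      else as.integer(r$dose_index)
    }, integer(1)),
    spo2_pct = vapply(recs, function(r) as.numeric(r$spo2_pct), numeric(1))
  )
}

#' Run a complete scenario end to end
#'
#' Generates the SpO2 trace for a named scenario (or explicit
#' [scenario_params()]), runs the closed loop against the device
#' configuration, and writes all artifacts to `out_dir`: `trace.csv` (the
#' trace as consumed by the controller), `events.jsonl`,
#' `trajectory_dose_<k>.csv` per attempted dose, and `manifest.json`. The
#' manifest summarizes each dose (cycle duration, injected volume, peak
#' needle force, insertion depth) and the alert time, and records the seed
#' and a config hash for reproducibility.
#'
#' @param config A `device_config`.
#' @param scenario Scenario preset name (see [scenario_preset()]) or a
#'   `scenario_params` object.
#' @param seed Integer seed for trace generation.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing files.
#' @param duration Trace duration, s.
#' @param rate Sampling rate, Hz.
#' @return A `run_manifest` list (invisibly if files were written).
#' @export
run_scenario <- function(config, scenario = "overdose-persistent", seed = 1,
                         out_dir = NULL, duration = 1500, rate = 1) {
  quiet_validate(config)
  scenario_name <- if (is.character(scenario)) scenario else "custom"
  params <- if (is.character(scenario)) scenario_preset(scenario) else scenario
  if (!inherits(params, "scenario_params")) {
    abort("scenario must be a preset name or scenario_params",
          class = "odrsim_param_error")
  }
  trace <- generate_spo2_trace(params, duration = duration, rate = rate,
                               seed = seed)
  res <- run_closed_loop(trace, config)
  doses <- res$log[res$log$kind == "DOSE", ]
  alerts <- res$log[res$log$kind == "ALERT", ]
  dose_summaries <- purrr::imap(res$trajectories, function(traj, nm) {
    g <- glance(traj)
    list(dose = nm, trigger_t_s = attr(traj, "trigger_t"),
         cycle_duration_s = g$duration_s, injected_ml = g$injected_ml,
         peak_force_n = g$peak_force_n,
         insertion_depth_mm = g$insertion_depth_mm, stalled = g$stalled)
  })
  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- c(outputs, write_spo2_csv(res$trace,
                                         file.path(out_dir, "trace.csv")))
    outputs <- c(outputs, write_events_jsonl(res$log,
                                             file.path(out_dir,
                                                       "events.jsonl")))
    for (i in seq_along(res$trajectories)) {
      p <- file.path(out_dir, paste0("trajectory_dose_", i, ".csv"))
      outputs <- c(outputs, write_trajectory_csv(res$trajectories[[i]], p))
    }
  }
  manifest <- structure(
    list(
      tool = "odrsim",
      version = as.character(utils::packageVersion("odrsim")),
      scenario = scenario_name,
      seed = seed,
      config_hash = rlang::hash(unclass(config)),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = basename(outputs),
      total_doses = nrow(doses),
      alert_time_s = if (nrow(alerts) > 0) alerts$t_s[1] else NA,
      doses = dose_summaries
    ),
    class = "run_manifest"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    return(invisible(manifest))
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> scenario '%s', seed %s: %d dose(s), alert at %s\n",
              x$scenario, x$seed, x$total_doses,
              if (is.na(x$alert_time_s)) "none" else
                paste0(x$alert_time_s, " s")))
  for (d in x$doses) {
    cat(sprintf("  %s: %.3f s, %.4f ml, peak %.3f N, depth %.2f mm%s\n",
                d$dose, d$cycle_duration_s, d$injected_ml, d$peak_force_n,
                d$insertion_depth_mm,
                if (isTRUE(d$stalled)) " [STALLED]" else ""))
  }
  invisible(x)
}
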