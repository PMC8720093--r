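#' Oxyhemoglobin dissociation curve (Severinghaus form)
#'
#' Closed-form blood O2 dissociation curve
#' `S = 1 / (23400 / (P^3 + 150 P) + 1)`, mapping arterial oxygen partial
#' pressure (mmHg) to hemoglobin saturation fraction. This is the mapping
#' behind the device's trigger rationale: 90 percent saturation corresponds
#' to a PaO2 near 60 mmHg, the accepted onset of hypoxia.
#'
#' @param pao2 PaO2 in mmHg (vector ok), strictly positive.
#' @return Saturation fraction in (0, 1).
#' @export
#' @examples
#' severinghaus_sao2(60)  # ~0.906
severinghaus_sao2 <- function(pao2) {
  if (any(!is.finite(pao2)) || any(pao2 <= 0)) {
    abort("pao2 must be finite and strictly positive",
          class = "odrsim_domain_error")
  }
  1 / (23400 / (pao2^3 + 150 * pao2) + 1)
}

#' Invert the dissociation curve
#'
#' Numerical inverse of [severinghaus_sao2()] by root-finding; round-trip
#' error below 1e-9 across the physiological range.
#'
#' @param sao2 Saturation fraction in (0, 1) (vector ok).
#' @return PaO2 in mmHg.
#' @export
#' @examples
#' inverse_severinghaus(0.90)  # ~58.8 mmHg, the 90% saturation point
inverse_severinghaus <- function(sao2) {
  if (any(!is.finite(sao2)) || any(sao2 <= 0) || any(sao2 >= 1)) {
    abort("sao2 must lie strictly between 0 and 1",
          class = "odrsim_domain_error")
  }
  vapply(sao2, function(s) {
    # S maps to x = P^3 + 150 P = 23400 S/(1-S); solve the monotone cubic
    target <- 23400 * s / (1 - s)
    uniroot(function(p) p^3 + 150 * p - target,
            lower = 1e-9, upper = 5000, tol = 1e-13)$root
  }, numeric(1))
}

#' Scenario parameters for synthetic SpO2 traces
#'
#' Defines the physiology the trace generator emulates: a normal baseline in
#' the accepted 93-97 percent band with Gaussian noise and a slow diurnal
#' sinusoid; an overdose as a deterministic desaturation ramp starting at
#' `overdose_onset`; and, optionally, antidote-driven recovery via a
#' one-compartment pharmacokinetic model with first-order absorption and an
#' 8 h elimination half-life.
#'
#' @param baseline_mean Baseline SpO2, percent; must lie in the normal
#'   93-97 band.
#' @param baseline_noise_sd Baseline Gaussian noise SD, percent.
#' @param diurnal_amplitude Diurnal sinusoid amplitude, percent.
#' @param diurnal_period Diurnal period, s.
#' @param overdose_onset Overdose start time, s (`Inf` = no overdose).
#' @param desaturation_rate Initial desaturation rate, percent/min.
#' @param floor Lowest SpO2 the desaturation reaches, percent.
#' @param desaturation_shape `"linear"` ramp or `"exponential"` approach to
#'   the floor (matched initial slope).
#' @param oximeter_noise_sd Optional oximeter measurement noise SD, percent,
#'   applied to every sample (0 keeps overdose traces deterministic after
#'   onset).
#' @param pk_feedback Should the closed loop feed dose times back into the
#'   trace through the recovery model?
#' @param nalmefene_half_life Antidote elimination half-life, h.
#' @param absorption_rate First-order absorption rate from the subcutaneous
#'   depot, 1/h (`Inf` = bolus).
#' @param effect_ec50 Concentration (relative units; one dose has unit
#'   amount) at half-maximal recovery drive.
#' @param recovery_rate Maximal recovery rate toward baseline, percent/min.
#' @return A `scenario_params` list.
#' @export
scenario_params <- function(baseline_mean = 95,
                            baseline_noise_sd = 0.5,
                            diurnal_amplitude = 0.5,
                            diurnal_period = 86400,
                            overdose_onset = Inf,
                            desaturation_rate = 4,
                            floor = 80,
                            desaturation_shape = c("linear", "exponential"),
                            oximeter_noise_sd = 0,
                            pk_feedback = FALSE,
                            nalmefene_half_life = 8,
                            absorption_rate = 20,
                            effect_ec50 = 0.2,
                            recovery_rate = 6) {
  desaturation_shape <- match.arg(desaturation_shape)
  if (baseline_mean < 93 || baseline_mean > 97) {
    abort("baseline_mean must lie in the normal 93-97% band",
          class = "odrsim_param_error")
  }
  if (floor < 0) {
    abort("floor must be non-negative", class = "odrsim_param_error")
  }
  if (nalmefene_half_life <= 0) {
    abort("nalmefene_half_life must be positive",
          class = "odrsim_param_error")
  }
  if (desaturation_rate <= 0) {
    abort("desaturation_rate must be positive",
          class = "odrsim_param_error")
  }
  structure(
    list(baseline_mean = baseline_mean,
         baseline_noise_sd = baseline_noise_sd,
         diurnal_amplitude = diurnal_amplitude,
         diurnal_period = diurnal_period,
         overdose_onset = overdose_onset,
         desaturation_rate = desaturation_rate,
         floor = floor,
         desaturation_shape = desaturation_shape,
         oximeter_noise_sd = oximeter_noise_sd,
         pk_feedback = pk_feedback,
         nalmefene_half_life = nalmefene_half_life,
         absorption_rate = absorption_rate,
         effect_ec50 = effect_ec50,
         recovery_rate = recovery_rate),
    class = "scenario_params"
  )
}

#' Generate a synthetic SpO2 trace
#'
#' Baseline samples are `baseline_mean + diurnal sinusoid + Gaussian noise`.
#' From `overdose_onset` the signal follows a deterministic desaturation
#' from the noise-free baseline level at onset down to `floor` (linear ramp
#' at `desaturation_rate`, or an exponential approach with the same initial
#' slope). Optional oximeter measurement noise is added to every sample.
#' Values are clipped to \[0, 100\]. The same seed and parameters always
#' reproduce the same trace.
#'
#' @param params A [scenario_params()] object.
#' @param duration Trace duration, s.
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed for the trace's RNG stream (`NULL` = use the
#'   current RNG state).
#' @return An `spo2_trace` tibble (`t_s`, `spo2_pct`) with attributes
#'   `seed` and `params`.
#' @export
#' @examples
#' tr <- generate_spo2_trace(scenario_params(overdose_onset = 300),
#'                           duration = 900, rate = 1, seed = 42)
generate_spo2_trace <- function(params, duration, rate = 1, seed = NULL) {
  if (!inherits(params, "scenario_params")) {
    abort("params must be a scenario_params object",
          class = "odrsim_param_error")
  }
  if (duration <= 0 || rate <= 0) {
    abort("duration and rate must be positive",
          class = "odrsim_param_error")
  }
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  det <- params$baseline_mean +
    params$diurnal_amplitude * sin(2 * pi * t / params$diurnal_period)
  draw <- function() {
    noise <- rnorm(n, 0, params$baseline_noise_sd)
    ox <- if (params$oximeter_noise_sd > 0) {
      rnorm(n, 0, params$oximeter_noise_sd)
    } else 0
    list(noise = noise, ox = ox)
  }
  r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  v <- det + r$noise
  if (is.finite(params$overdose_onset) && params$overdose_onset <= duration) {
    post <- t >= params$overdose_onset
    start <- params$baseline_mean + params$diurnal_amplitude *
      sin(2 * pi * params$overdose_onset / params$diurnal_period)
    dt_post <- t[post] - params$overdose_onset
    ramp <- if (params$desaturation_shape == "linear") {
      start - params$desaturation_rate * dt_post / 60
    } else {
      # exponential approach with the same initial slope
      kdes <- params$desaturation_rate / 60 / max(start - params$floor, 1e-9)
      params$floor + (start - params$floor) * exp(-kdes * dt_post)
    }
    v[post] <- pmax(ramp, params$floor)
  }
  v <- pmin(pmax(v + r$ox, 0), 100)
  structure(
    tibble(t_s = t, spo2_pct = v),
    class = c("spo2_trace", class(tibble())),
    seed = seed,
    params = params
  )
}

#' Antidote plasma concentration
#'
#' One-compartment model with first-order absorption from the subcutaneous
#' depot and first-order elimination (`k_e = ln 2 / half-life`), superposed
#' over doses of unit amount:
#' `C(t) = sum_d ka/(ka-ke) (exp(-ke tau_d) - exp(-ka tau_d))`, `tau_d >= 0`.
#' With `absorption_rate = Inf` each dose is a bolus and the concentration
#' decays purely by elimination, halving every half-life.
#'
#' @param t Times, s.
#' @param dose_times Dose times, s.
#' @param params A [scenario_params()] object.
#' @return Concentration in relative units (one dose has unit amount).
#' @export
pk_concentration <- function(t, dose_times, params) {
  ke <- log(2) / (params$nalmefene_half_life * 3600)
  ka <- params$absorption_rate / 3600
  conc <- numeric(length(t))
  for (td in dose_times) {
    tau <- pmax(t - td, 0)
    on <- t >= td
    ci <- if (!is.finite(ka)) {
      exp(-ke * tau)
    } else if (abs(ka - ke) < 1e-15) {
      ka * tau * exp(-ke * tau)
    } else {
      ka / (ka - ke) * (exp(-ke * tau) - exp(-ka * tau))
    }
    conc <- conc + ci * on
  }
  conc
}

#' Apply antidote-driven recovery to a trace
#'
#' Pharmacodynamic link from antidote concentration to the SpO2 signal: the
#' trace is re-integrated on its own sample grid, adding to each baseline
#' increment a recovery drive toward `baseline_mean` at `recovery_rate`
#' scaled by the saturable occupancy term `C / (C + effect_ec50)`. With zero
#' doses (or zero effect) the trace is returned unchanged.
#'
#' @param trace An `spo2_trace`.
#' @param dose_times Dose times, s; must fall within the trace span.
#' @param params A [scenario_params()] object.
#' @return A modified `spo2_trace` (attributes preserved).
#' @export
apply_dose_response <- function(trace, dose_times, params) {
  if (length(dose_times) == 0) return(trace)
  if (any(dose_times < min(trace$t_s)) || any(dose_times > max(trace$t_s))) {
    abort("dose_times must fall within the trace time span",
          class = "odrsim_domain_error")
  }
  t <- trace$t_s
  base <- trace$spo2_pct
  conc <- pk_concentration(t, dose_times, params)
  occ <- conc / (conc + params$effect_ec50)
  rr <- params$recovery_rate / 60  # percent per second
  v <- base
  for (i in seq_along(t)[-1]) {
    dt <- t[i] - t[i - 1]
    db <- base[i] - base[i - 1]
    v[i] <- v[i - 1] + db +
      rr * occ[i - 1] * (params$baseline_mean - v[i - 1]) * dt
  }
  v <- pmin(pmax(v, 0), 100)
  out <- trace
  out$spo2_pct <- v
  out
}

#' Named scenario presets
#'
#' `"normal"`: baseline only, no overdose. `"overdose-persistent"`: an
#' overdose ramp at 600 s with no recovery, so the full three-dose schedule
#' runs. `"overdose-recovery"`: the same overdose with pharmacokinetic
#' feedback enabled, so the first dose restores saturation before the
#' 5-minute recheck. Overdose desaturation rates are illustrative (4
#' percent/min to a floor of 80 percent).
#'
#' @param name Preset name.
#' @return A `scenario_params` object.
#' @export
scenario_preset <- function(name = c("normal", "overdose-persistent",
                                     "overdose-recovery")) {
  name <- match.arg(name)
  switch(
    name,
    "normal" = scenario_params(),
    "overdose-persistent" = scenario_params(overdose_onset = 600,
                                            desaturation_rate = 4,
                                            floor = 80),
    "overdose-recovery" = scenario_params(overdose_onset = 600,
                                          desaturation_rate = 4,
                                          floor = 80,
                                          pk_feedback = TRUE,
                                          absorption_rate = 30,
                                          effect_ec50 = 0.1,
                                          recovery_rate = 8)
  )
}
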