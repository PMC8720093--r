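#' Poiseuille hydraulic resistance of the hypodermic needle
#'
#' Laminar-tube (Hagen-Poiseuille) resistance `R = 8 mu L / (pi r^4)` with
#' dynamic viscosity `mu = kinematic viscosity * density`. Needle flow is
#' then `Q = dP / R`.
#'
#' @param config A `device_config`.
#' @return Resistance in Pa.s/m^3.
#' @export
#' @examples
#' needle_resistance(device_config())  # ~1.64e9 Pa.s/m^3 for a 30 G, 8 mm needle
needle_resistance <- function(config) {
  quiet_validate(config)
  si <- as_si(config)
  si$R_needle
}

#' Resistive force on the needle assembly
#'
#' Piecewise force law for needle travel `depth` (measured from the stowed
#' position): a puncture peak while the tip crosses the sterile membrane
#' (travel below the stow gap `membrane_standoff`), then elastic plus viscous
#' tissue resistance once in tissue:
#' `F = F_punct * gate(depth) + k_t * (depth - standoff)+ + b_t * (velocity)+`.
#' The puncture gate is a unit trapezoid over the membrane zone whose edges
#' are regularized over `puncture_ramp` so the force is continuous in depth
#' (a hard step makes the insertion ODE chatter); the force at exactly zero
#' travel is zero.
#'
#' @param depth Needle travel from stow, m (vector ok).
#' @param velocity Needle velocity, m/s (recycled).
#' @param config A `device_config`.
#' @return Force in N.
#' @export
tissue_force <- function(depth, velocity, config) {
  si <- as_si(config)
  if (any(!is.finite(depth)) || any(depth < 0)) {
    abort("depth must be finite and non-negative",
          class = "odrsim_domain_error")
  }
  w <- max(si$ramp, 1e-9)
  gate <- pmax(0, pmin(1, depth / w, (si$standoff - depth) / w))
  if (si$standoff <= 0) gate <- 0
  si$F_punct * gate +
    si$k_t * pmax(depth - si$standoff, 0) +
    si$b_t * pmax(velocity, 0)
}

#' Initial device state
#'
#' The READY state at the moment of triggering: fluid piston at its initial
#' displacement, needle stowed, lower compartment at the fluid-side initial
#' pressure, reservoir fully charged, nothing injected.
#'
#' @param config A `device_config`.
#' @return A `device_state` (named list).
#' @export
device_ready_state <- function(config) {
  si <- as_si(config)
  structure(
    list(
      t = 0,
      x_main = si$x0, v_main = 0,
      x_needle = 0, v_needle = 0,
      pv_lower = si$P_fluid0 * (si$A_f * si$x0 + si$V_dead),
      pv_reservoir = si$P_gas0 * si$V_gas,
      v_injected = 0,
      phase = "READY"
    ),
    class = "device_state"
  )
}

# Gas-inventory transfer through the linear valve. Inventories are tracked
# as pressure*volume (Pa.m^3); transfer referenced to upstream pressure so
# the summed inventory is conserved. The valve is a check valve: reservoir
# to lower compartment only.
valve_pv_flow <- function(pv_lower, pv_reservoir, x_main, si) {
  p_low <- pv_lower / (si$A_f * x_main + si$V_dead)
  p_res <- pv_reservoir / si$V_gas
  q <- si$Cv * max(p_res - p_low, 0)
  p_res * q
}

#' Time derivatives of the device state
#'
#' The two-phase dynamics contract. With the valve open, gas inventory moves
#' from reservoir to lower compartment at `Cv * (P_res - P_low)` volumetric
#' flow referenced to upstream pressure. While INSERTING, the incompressible
#' antidote rigidly couples the pistons (`A_f dx_main = A_n dx_needle`, no
#' needle outflow) and the assembly accelerates under the gas pressure force
#' against spring, dashpot and tissue resistance. While INFUSING, the needle
#' assembly is held by the stop ring and flow through the needle is
#' quasi-static Poiseuille: `Q = (P_fluid - P_tissue) / R_needle`.
#'
#' @param state A `device_state`.
#' @param config A `device_config`.
#' @param valve_open Is the gas valve open?
#' @return Named list of derivatives of each numeric state field.
#' @export
device_derivatives <- function(state, config, valve_open = TRUE) {
  si <- as_si(config)
  num <- unlist(state[c("x_main", "v_main", "x_needle", "v_needle",
                        "pv_lower", "pv_reservoir", "v_injected")])
  if (any(!is.finite(num))) {
    abort(paste0("non-finite device state at t = ", state$t, ": ",
                 paste(names(num)[!is.finite(num)], collapse = ", ")),
          class = "odrsim_integration_error")
  }
  d <- list(x_main = 0, v_main = 0, x_needle = 0, v_needle = 0,
            pv_lower = 0, pv_reservoir = 0, v_injected = 0)
  if (!valve_open && state$phase %in% c("READY", "DONE")) {
    return(d)
  }
  if (valve_open) {
    dpv <- valve_pv_flow(state$pv_lower, state$pv_reservoir, state$x_main, si)
    d$pv_lower <- dpv
    d$pv_reservoir <- -dpv
  }
  p_low <- state$pv_lower / (si$A_f * state$x_main + si$V_dead)
  if (state$phase %in% c("READY", "INSERTING")) {
    xn <- state$x_needle
    vn <- si$ratio * state$v_main
    f_res <- tissue_force(max(xn, 0), vn, config) +
      si$k * max(xn, 0) + si$b * vn
    acc <- (si$A_f * (p_low - P_ATM) - si$ratio * f_res) / si$m
    d$x_main <- state$v_main
    d$v_main <- acc
    d$x_needle <- si$ratio * state$v_main
    d$v_needle <- si$ratio * acc
  } else if (state$phase == "INFUSING") {
    q <- max(p_low - si$P_back, 0) / si$R_needle
    d$x_main <- q / si$A_f
    d$v_injected <- q
  }
  d
}

#' Simulate one injection cycle
#'
#' Integrates the device from a READY state (or from the terminal state of a
#' previous cycle, for repeat doses) through needle insertion and infusion,
#' with event detection at (a) the injection piston reaching full stroke
#' (INSERTING to INFUSING), (b) the programmed `dose_volume` being delivered
#' (valve closed, DONE), and (c) the fluid piston reaching full stroke
#' (reservoir exhausted). When the gas charge cannot finish the dose the
#' trajectory is returned with `attr(, "stalled") = TRUE` and a terminal
#' phase other than DONE.
#'
#' Stiff-capable integration (`deSolve::lsoda`) with root-finding events,
#' relative tolerance 1e-8, absolute 1e-12; the returned trajectory is
#' sampled on a fixed 1 ms grid.
#'
#' @param config A `device_config`.
#' @param initial A `device_state`; default [device_ready_state()]. A state
#'   with the needle already at full stroke starts directly in INFUSING
#'   (repeat dose).
#' @param t_max Simulated-time cap per cycle, s.
#' @param dt_out Output grid spacing, s.
#' @return A `device_trajectory`: a tibble with columns `t_s, x_main_m,
#'   v_main_ms, x_needle_m, v_needle_ms, p_lower_pa, p_fluid_pa, flow_m3s,
#'   v_injected_ml, force_n, phase`, plus attributes `events` (tibble of
#'   `event`, `t_s`), `stalled`, `final_state` and `config`.
#' @export
#' @examples
#' traj <- simulate_cycle(device_preset("default"))
#' glance(traj)
simulate_cycle <- function(config, initial = NULL, t_max = 120,
                           dt_out = 1e-3) {
  quiet_validate(config)
  si <- as_si(config)
  if (is.null(initial)) initial <- device_ready_state(config)
  if (!inherits(initial, "device_state")) {
    abort("initial must be a device_state", class = "odrsim_domain_error")
  }
  stall_margin <- 100  # Pa above back-pressure below which nothing can flow
  events <- tibble(event = character(), t_s = numeric())
  stalled <- FALSE
  segs <- list()
  t_off <- 0
  xm <- initial$x_main
  xn <- initial$x_needle
  pv_l <- initial$pv_lower
  pv_r <- initial$pv_reservoir
  v_inj0 <- initial$v_injected

  at_stroke <- xn >= si$stroke_n - 1e-9

  if (!at_stroke) {
    # --- INSERTING: pistons rigidly coupled through the incompressible fluid
    xm0 <- xm
    xn0 <- xn
    rhs_ins <- function(t, y, p) {
      xmc <- y[1]; vm <- y[2]
      xnc <- xn0 + si$ratio * (xmc - xm0)
      vn <- si$ratio * vm
      p_low <- y[3] / (si$A_f * xmc + si$V_dead)
      dpv <- valve_pv_flow(y[3], y[4], xmc, si)
      w <- max(si$ramp, 1e-9)
      gate <- max(0, min(1, max(xnc, 0) / w, (si$standoff - xnc) / w))
      f_t <- si$F_punct * gate + si$k_t * max(xnc - si$standoff, 0) +
        si$b_t * max(vn, 0)
      f_res <- f_t + si$k * max(xnc, 0) + si$b * vn
      acc <- (si$A_f * (p_low - P_ATM) - si$ratio * f_res) / si$m
      list(c(vm, acc, dpv, -dpv))
    }
    root_ins <- function(t, y, p) {
      p_low <- y[3] / (si$A_f * y[1] + si$V_dead)
      p_res <- y[4] / si$V_gas
      # stall either when the whole gas inventory is near ambient, or when
      # reservoir and lower compartment have equalized short of full stroke
      # (static equilibrium against the tissue force; no drive left)
      c(xn0 + si$ratio * (y[1] - xm0) - si$stroke_n,
        y[1] - si$stroke_f,
        max(p_low, p_res) - P_ATM - stall_margin,
        p_res - p_low - 2000)
    }
    out <- deSolve::lsoda(
      c(xm, initial$v_main, pv_l, pv_r),
      times = seq(0, t_max, by = dt_out),
      func = rhs_ins, parms = NULL,
      rtol = 1e-8, atol = 1e-12,
      events = list(root = TRUE), rootfunc = root_ins, maxsteps = 500000
    )
    dimnames(out) <- NULL
    if (any(!is.finite(out[nrow(out), ]))) {
      abort("integration failed during INSERTING",
            class = "odrsim_integration_error")
    }
    n <- nrow(out)
    seg <- tibble(
      t_s = out[, 1],
      x_main_m = out[, 2],
      v_main_ms = out[, 3],
      x_needle_m = xn0 + si$ratio * (out[, 2] - xm0),
      v_needle_ms = si$ratio * out[, 3],
      pv_lower = out[, 4],
      pv_reservoir = out[, 5],
      v_injected_m3 = v_inj0,
      phase = "INSERTING"
    )
    segs[[length(segs) + 1]] <- seg
    troot <- attr(out, "troot")
    iroot <- attr(out, "iroot")
    fired <- if (is.null(iroot)) integer() else which(iroot == 1)
    xm <- out[n, 2]
    xn <- xn0 + si$ratio * (xm - xm0)
    pv_l <- out[n, 4]
    pv_r <- out[n, 5]
    t_off <- out[n, 1]
    if (length(troot) == 0 || length(fired) == 0) {
      stalled <- TRUE
      events <- dplyr::bind_rows(events,
                                 tibble(event = "stalled", t_s = t_off))
    } else if (1 %in% fired) {
      events <- dplyr::bind_rows(events,
                                 tibble(event = "insert_complete",
                                        t_s = t_off))
      at_stroke <- TRUE
    } else if (2 %in% fired) {
      stalled <- TRUE
      events <- dplyr::bind_rows(events,
                                 tibble(event = "exhausted", t_s = t_off))
    } else {
      stalled <- TRUE
      events <- dplyr::bind_rows(events,
                                 tibble(event = "stalled", t_s = t_off))
    }
  }

  dose_done <- FALSE
  if (at_stroke && !stalled) {
    # --- INFUSING: needle held by the stop ring; quasi-static viscous flow
    rhs_inf <- function(t, y, p) {
      p_low <- y[2] / (si$A_f * y[1] + si$V_dead)
      dpv <- valve_pv_flow(y[2], y[3], y[1], si)
      q <- max(p_low - si$P_back, 0) / si$R_needle
      list(c(q / si$A_f, dpv, -dpv, q))
    }
    root_inf <- function(t, y, p) {
      p_low <- y[2] / (si$A_f * y[1] + si$V_dead)
      p_res <- y[3] / si$V_gas
      c(y[4] - si$dose,
        y[1] - si$stroke_f,
        max(p_low, p_res) - si$P_back - stall_margin)
    }
    out <- deSolve::lsoda(
      c(xm, pv_l, pv_r, 0),
      times = seq(0, t_max - t_off, by = dt_out),
      func = rhs_inf, parms = NULL,
      rtol = 1e-8, atol = 1e-12,
      events = list(root = TRUE), rootfunc = root_inf, maxsteps = 500000
    )
    dimnames(out) <- NULL
    if (any(!is.finite(out[nrow(out), ]))) {
      abort("integration failed during INFUSING",
            class = "odrsim_integration_error")
    }
    n <- nrow(out)
    seg <- tibble(
      t_s = t_off + out[, 1],
      x_main_m = out[, 2],
      v_main_ms = 0,
      x_needle_m = si$stroke_n,
      v_needle_ms = 0,
      pv_lower = out[, 3],
      pv_reservoir = out[, 4],
      v_injected_m3 = v_inj0 + out[, 5],
      phase = "INFUSING"
    )
    # drop the duplicated seam sample
    if (length(segs) > 0) seg <- seg[-1, , drop = FALSE]
    segs[[length(segs) + 1]] <- seg
    troot <- attr(out, "troot")
    iroot <- attr(out, "iroot")
    fired <- if (is.null(iroot)) integer() else which(iroot == 1)
    xm <- out[n, 2]
    pv_l <- out[n, 3]
    pv_r <- out[n, 4]
    v_inj_end <- v_inj0 + out[n, 5]
    t_end <- t_off + out[n, 1]
    if (length(troot) == 0 || length(fired) == 0) {
      stalled <- TRUE
      events <- dplyr::bind_rows(events,
                                 tibble(event = "stalled", t_s = t_end))
    } else if (1 %in% fired) {
      dose_done <- TRUE
      events <- dplyr::bind_rows(events,
                                 tibble(event = "dose_complete", t_s = t_end))
    } else if (2 %in% fired) {
      stalled <- TRUE
      events <- dplyr::bind_rows(events,
                                 tibble(event = "exhausted", t_s = t_end))
    } else {
      stalled <- TRUE
      events <- dplyr::bind_rows(events,
                                 tibble(event = "stalled", t_s = t_end))
    }
    v_inj0 <- v_inj_end
  }

  traj <- dplyr::bind_rows(segs)
  # derived channels
  p_low <- traj$pv_lower / (si$A_f * traj$x_main_m + si$V_dead)
  flow <- ifelse(traj$phase == "INFUSING",
                 pmax(p_low - si$P_back, 0) / si$R_needle, 0)
  force <- tissue_force(pmax(traj$x_needle_m, 0),
                        pmax(traj$v_needle_ms, 0), config)
  traj <- tibble(
    t_s = traj$t_s,
    x_main_m = traj$x_main_m,
    v_main_ms = traj$v_main_ms,
    x_needle_m = traj$x_needle_m,
    v_needle_ms = traj$v_needle_ms,
    p_lower_pa = p_low,
    p_fluid_pa = p_low,
    flow_m3s = flow,
    v_injected_ml = traj$v_injected_m3 * 1e6,
    force_n = force,
    phase = traj$phase,
    pv_lower = traj$pv_lower,
    pv_reservoir = traj$pv_reservoir
  )
  final_phase <- if (dose_done) "DONE" else utils::tail(traj$phase, 1)
  final_state <- structure(
    list(
      t = utils::tail(traj$t_s, 1),
      x_main = xm, v_main = 0,
      x_needle = utils::tail(traj$x_needle_m, 1), v_needle = 0,
      pv_lower = pv_l, pv_reservoir = pv_r,
      v_injected = v_inj0,
      phase = final_phase
    ),
    class = "device_state"
  )
  structure(
    traj,
    class = c("device_trajectory", class(traj)),
    events = events,
    stalled = stalled,
    final_state = final_state,
    config = config
  )
}

#' Needle insertion depth
#'
#' Tissue penetration depth: needle travel beyond the membrane stow gap,
#' `max(0, x_needle - membrane_standoff)`, in mm. Equals `needle_length` at
#' full piston stroke.
#'
#' @param state A `device_state`, or a numeric vector of needle positions in
#'   metres.
#' @param config A `device_config`.
#' @return Depth in mm.
#' @export
insertion_depth <- function(state, config) {
  si <- as_si(config)
  xn <- if (inherits(state, "device_state")) state$x_needle else state
  if (any(!is.finite(xn))) {
    abort("needle position must be finite", class = "odrsim_domain_error")
  }
  pmax(0, xn - si$standoff) * 1e3
}

#' @export
print.device_state <- function(x, ...) {
  cat(sprintf(
    "<device_state> t %.4g s, phase %s | x_main %.4g mm, x_needle %.4g mm, injected %.4g ml\n",
    x$t, x$phase, x$x_main * 1e3, x$x_needle * 1e3, x$v_injected * 1e6))
  invisible(x)
}

#' @export
print.device_trajectory <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("<device_trajectory> %d samples over %.3f s%s\n",
              nrow(x), utils::tail(x$t_s, 1),
              if (isTRUE(attr(x, "stalled"))) " [STALLED]" else ""))
  if (nrow(ev) > 0) {
    cat(paste0("  ", ev$event, " @ ", signif(ev$t_s, 4), " s",
               collapse = "\n"), "\n")
  }
  NextMethod()
}
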