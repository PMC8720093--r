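#' Device configuration
#'
#' Build the full mechanical and control configuration of the wearable
#' autoinjector. External values use the engineering units the device is
#' specified in (cm, mm, atm, cSt, g); they are converted to SI once, by
#' [as_si()], before any simulation. All arguments have defaults matching the
#' shipped `"default"` preset: the published device dimensions and drug
#' properties, plus the design parameters the dimensional tables leave free
#' (valve conductance, tissue-force law, membrane standoff, gas charge).
#'
#' The `"table1"` preset keeps the published 5 atm gas charge verbatim. That
#' charge cannot displace the full three-dose volume against ambient
#' pressure, so validation emits a gas-budget warning for it; the default
#' preset carries a 20 atm charge, which completes all three doses with
#' margin.
#'
#' @param fluid_piston_radius Fluid (main) piston radius, cm.
#' @param fluid_piston_stroke Fluid piston stroke, cm.
#' @param fluid_piston_initial_displacement Initial fluid-piston offset, cm;
#'   keeps the starting lower-compartment volume nonzero.
#' @param dead_volume Residual lower-compartment volume at zero displacement,
#'   cm^3; prevents a singular start-up pressure.
#' @param fluid_initial_pressure Initial lower-compartment gas pressure, atm.
#' @param needle_piston_radius Injection (needle) piston radius, cm.
#' @param needle_piston_stroke Injection piston stroke, cm.
#' @param needle_inner_diameter Hypodermic needle internal diameter, mm.
#' @param needle_length Needle length, mm (30 gauge, 8 mm).
#' @param chassis_mass Lumped moving-assembly inertia, g.
#' @param spring_constant Retention spring stiffness to chassis, N/m.
#' @param dashpot_coefficient Retention damper coefficient, N.s/m.
#' @param gas_initial_pressure Compressed-gas reservoir charge, atm.
#' @param gas_radius Gas reservoir radius, cm.
#' @param gas_height Gas reservoir height, cm.
#' @param fluid_viscosity Antidote kinematic viscosity, cSt.
#' @param fluid_density Antidote density, kg/m^3.
#' @param wall_allowance_length Wall allowance added to the compartment
#'   length when reporting external dimensions, cm.
#' @param membrane_standoff Travel between needle tip at rest and the skin
#'   surface (the sterile-membrane stow gap), mm. Default
#'   `needle_piston_stroke * 10 - needle_length`, so full piston travel gives
#'   exactly `needle_length` of tissue insertion.
#' @param valve_conductance Linear gas-valve conductance, m^3/(Pa.s);
#'   volumetric flow per unit pressure difference, referenced to upstream
#'   pressure. Calibrated so the default first cycle completes in about 0.9 s.
#' @param tissue_force_params Named list: `puncture_force` (N, membrane
#'   puncture peak), `tissue_stiffness` (N/m), `tissue_damping` (N.s/m),
#'   `puncture_ramp` (mm, regularization width of the puncture-force edges).
#' @param tissue_back_pressure Subcutaneous back-pressure, atm gauge.
#' @param dose_volume Volume per dose, ml.
#' @param max_doses Maximum doses per episode.
#' @param redose_interval Interval between dose re-checks, s.
#' @param spo2_threshold Trigger threshold, percent SpO2.
#' @param persistence_samples Consecutive at-or-below-threshold samples
#'   required to trigger (1 = single-sample triggering).
#'
#' @return An object of class `device_config` (named list).
#' @seealso [device_preset()], [validate_device_config()], [as_si()],
#'   [reservoir_capacity()], [required_length()], [gas_displaceable_volume()]
#' @export
#' @examples
#' cfg <- device_config()
#' reservoir_capacity(cfg)
#' required_length(cfg, include_walls = TRUE)
device_config <- function(fluid_piston_radius = 1.07,
                          fluid_piston_stroke = 1.1,
                          fluid_piston_initial_displacement = 0.01,
                          dead_volume = 1e-5,
                          fluid_initial_pressure = 1,
                          needle_piston_radius = 0.5,
                          needle_piston_stroke = 1.1,
                          needle_inner_diameter = 0.6,
                          needle_length = 8,
                          chassis_mass = 500,
                          spring_constant = 11,
                          dashpot_coefficient = 11,
                          gas_initial_pressure = 20,
                          gas_radius = 0.3,
                          gas_height = 0.9,
                          fluid_viscosity = 0.658,
                          fluid_density = 992.562,
                          wall_allowance_length = 0.86,
                          membrane_standoff = NULL,
                          valve_conductance = 9e-14,
                          tissue_force_params = list(),
                          tissue_back_pressure = 0,
                          dose_volume = 1,
                          max_doses = 3L,
                          redose_interval = 300,
                          spo2_threshold = 90,
                          persistence_samples = 1L) {
  if (is.null(membrane_standoff)) {
    membrane_standoff <- needle_piston_stroke * 10 - needle_length
  }
  tfp <- modifyList(
    list(puncture_force = 1.6, tissue_stiffness = 220,
         tissue_damping = 2, puncture_ramp = 0.2),
    as.list(tissue_force_params)
  )
  extra <- setdiff(names(tfp), c("puncture_force", "tissue_stiffness",
                                 "tissue_damping", "puncture_ramp"))
  if (length(extra) > 0) {
    abort(paste0("unknown tissue_force_params field: ", extra[1]),
          class = "odrsim_config_error")
  }
  cfg <- structure(
    list(
      fluid_piston_radius = fluid_piston_radius,
      fluid_piston_stroke = fluid_piston_stroke,
      fluid_piston_initial_displacement = fluid_piston_initial_displacement,
      dead_volume = dead_volume,
      fluid_initial_pressure = fluid_initial_pressure,
      needle_piston_radius = needle_piston_radius,
      needle_piston_stroke = needle_piston_stroke,
      needle_inner_diameter = needle_inner_diameter,
      needle_length = needle_length,
      chassis_mass = chassis_mass,
      spring_constant = spring_constant,
      dashpot_coefficient = dashpot_coefficient,
      gas_initial_pressure = gas_initial_pressure,
      gas_radius = gas_radius,
      gas_height = gas_height,
      fluid_viscosity = fluid_viscosity,
      fluid_density = fluid_density,
      wall_allowance_length = wall_allowance_length,
      membrane_standoff = membrane_standoff,
      valve_conductance = valve_conductance,
      tissue_force_params = tfp,
      tissue_back_pressure = tissue_back_pressure,
      dose_volume = dose_volume,
      max_doses = as.integer(max_doses),
      redose_interval = redose_interval,
      spo2_threshold = spo2_threshold,
      persistence_samples = as.integer(persistence_samples)
    ),
    class = "device_config"
  )
  validate_device_config(cfg)
}

#' Named device presets
#'
#' `"default"` is the calibrated configuration used throughout: published
#' dimensions with a 20 atm gas charge and a pinned valve conductance so the
#' first injection cycle completes within the 1.2 s design milestone.
#' `"table1"` reproduces the published simulation parameter table verbatim,
#' including its 5 atm gas charge (which triggers a gas-budget warning: it
#' cannot complete three 1 ml doses).
#'
#' @param name `"default"` or `"table1"`.
#' @return A `device_config`.
#' @export
#' @examples
#' cfg <- device_preset("default")
device_preset <- function(name = c("default", "table1")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "odrsim")
  load_config(path)$device
}

#' Validate a device configuration
#'
#' Checks physical self-consistency: strict positivity of all dimensional
#' fields, that full needle insertion is reachable within the injection-piston
#' stroke, that the antidote reservoir holds the full dosing schedule, and
#' that the SpO2 threshold is a percentage. A gas charge too small to
#' displace `dose_volume * max_doses` against ambient pressure raises a
#' warning (class `odrsim_gas_budget_warning`), not an error.
#'
#' @param config A `device_config`.
#' @return `config`, invisibly, if valid; otherwise an error of class
#'   `odrsim_config_error` naming the offending field.
#' @export
validate_device_config <- function(config) {
  if (!inherits(config, "device_config")) {
    abort("config must be a device_config object",
          class = "odrsim_config_error")
  }
  positive <- c(
    "fluid_piston_radius", "fluid_piston_stroke",
    "fluid_piston_initial_displacement", "dead_volume",
    "fluid_initial_pressure", "needle_piston_radius", "needle_piston_stroke",
    "needle_inner_diameter", "needle_length", "chassis_mass",
    "gas_initial_pressure", "gas_radius", "gas_height", "fluid_viscosity",
    "fluid_density", "dose_volume", "redose_interval"
  )
  for (f in positive) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("field '", f, "' must be a single positive number"),
            class = "odrsim_config_error")
    }
  }
  nonneg <- c("spring_constant", "dashpot_coefficient",
              "wall_allowance_length", "membrane_standoff",
              "valve_conductance", "tissue_back_pressure")
  for (f in nonneg) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort(paste0("field '", f, "' must be a single non-negative number"),
            class = "odrsim_config_error")
    }
  }
  tfp <- config$tissue_force_params
  for (f in c("puncture_force", "tissue_stiffness", "tissue_damping",
              "puncture_ramp")) {
    if (!is.numeric(tfp[[f]]) || tfp[[f]] < 0) {
      abort(paste0("field 'tissue_force_params$", f,
                   "' must be non-negative"),
            class = "odrsim_config_error")
    }
  }
  if (config$max_doses < 1) {
    abort("field 'max_doses' must be at least 1",
          class = "odrsim_config_error")
  }
  if (config$spo2_threshold <= 0 || config$spo2_threshold >= 100) {
    abort("field 'spo2_threshold' must lie strictly between 0 and 100",
          class = "odrsim_config_error")
  }
  # full insertion must be reachable: stroke (cm -> mm) covers needle + stow gap
  if (config$needle_piston_stroke * 10 <
      config$needle_length + config$membrane_standoff - 1e-9) {
    abort(paste0("field 'needle_piston_stroke' too short: needle_length + ",
                 "membrane_standoff exceeds the stroke"),
          class = "odrsim_config_error")
  }
  schedule_ml <- config$dose_volume * config$max_doses
  if (schedule_ml > reservoir_capacity(config, .validate = FALSE) + 1e-9) {
    abort(paste0("field 'dose_volume': dose_volume * max_doses exceeds the ",
                 "antidote reservoir capacity"),
          class = "odrsim_config_error")
  }
  budget <- gas_displaceable_volume(config, back_pressure = 1,
                                    .validate = FALSE)
  if (budget < schedule_ml) {
    warn(paste0("gas budget: the compressed-gas charge can displace only ",
                signif(budget, 4), " cm^3 at ambient back-pressure, below ",
                "the programmed ", schedule_ml, " ml dosing schedule"),
         class = "odrsim_gas_budget_warning")
  }
  invisible(config)
}

#' Convert a device configuration to SI units
#'
#' Performs the single external-to-SI unit conversion (cm, mm, atm, cSt, g
#' to m, Pa, m^2/s, kg) and precomputes the derived quantities the dynamics
#' use: piston areas, their ratio, gas-reservoir volume, dynamic viscosity
#' and the Poiseuille needle resistance.
#'
#' @param config A `device_config`.
#' @return A named list of SI scalars.
#' @export
as_si <- function(config) {
  tfp <- config$tissue_force_params
  si <- list(
    r_f = config$fluid_piston_radius * 1e-2,
    stroke_f = config$fluid_piston_stroke * 1e-2,
    x0 = config$fluid_piston_initial_displacement * 1e-2,
    V_dead = config$dead_volume * 1e-6,
    P_fluid0 = config$fluid_initial_pressure * P_ATM,
    r_n = config$needle_piston_radius * 1e-2,
    stroke_n = config$needle_piston_stroke * 1e-2,
    r_needle = config$needle_inner_diameter * 1e-3 / 2,
    L_needle = config$needle_length * 1e-3,
    m = config$chassis_mass * 1e-3,
    k = config$spring_constant,
    b = config$dashpot_coefficient,
    P_gas0 = config$gas_initial_pressure * P_ATM,
    nu = config$fluid_viscosity * 1e-6,
    rho = config$fluid_density,
    standoff = config$membrane_standoff * 1e-3,
    Cv = config$valve_conductance,
    F_punct = tfp$puncture_force,
    k_t = tfp$tissue_stiffness,
    b_t = tfp$tissue_damping,
    ramp = tfp$puncture_ramp * 1e-3,
    P_back = P_ATM + config$tissue_back_pressure * P_ATM,
    dose = config$dose_volume * 1e-6
  )
  si$V_gas <- pi * (config$gas_radius * 1e-2)^2 * (config$gas_height * 1e-2)
  si$A_f <- pi * si$r_f^2
  si$A_n <- pi * si$r_n^2
  si$ratio <- si$A_f / si$A_n
  si$mu <- si$nu * si$rho
  si$R_needle <- 8 * si$mu * si$L_needle / (pi * si$r_needle^4)
  si
}


# Revalidation inside operations: structural errors still throw, but the
# construction-time gas-budget warning is not repeated on every call.
quiet_validate <- function(config) {
  withCallingHandlers(
    validate_device_config(config),
    odrsim_gas_budget_warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Antidote reservoir capacity
#'
#' Maximum antidote volume the upper fluid compartment can hold:
#' `pi * r^2 * stroke` of the fluid piston, in ml.
#'
#' @param config A `device_config`.
#' @param .validate Internal; skip re-validation.
#' @return Capacity in ml.
#' @export
#' @examples
#' reservoir_capacity(device_config())  # ~3.956 ml, holds three 1 ml doses
reservoir_capacity <- function(config, .validate = TRUE) {
  if (.validate) quiet_validate(config)
  pi * config$fluid_piston_radius^2 * config$fluid_piston_stroke
}

#' Compartment length requirement
#'
#' The fluid and injection compartments sit side by side; their diameters sum
#' to the internal length. With `include_walls = TRUE`, the wall allowance is
#' added to give the device's external length.
#'
#' @param config A `device_config`.
#' @param include_walls Add `wall_allowance_length`?
#' @return Length in cm.
#' @export
#' @examples
#' required_length(device_config())                        # 3.14 cm
#' required_length(device_config(), include_walls = TRUE)  # 4.00 cm
required_length <- function(config, include_walls = FALSE) {
  quiet_validate(config)
  len <- 2 * config$fluid_piston_radius + 2 * config$needle_piston_radius
  if (include_walls) len <- len + config$wall_allowance_length
  len
}

#' Gas budget under isothermal expansion
#'
#' Maximum lower-compartment volume that the compressed-gas reservoir can
#' fill at a pressure at least `back_pressure`, assuming isothermal
#' ideal-gas (Boyle's law) expansion:
#' `V = P0 * V_res / back_pressure - V_res`, floored at zero.
#'
#' @param config A `device_config`.
#' @param back_pressure Back-pressure in atm (>= 1).
#' @param .validate Internal; skip re-validation.
#' @return Displaceable volume in cm^3.
#' @export
#' @examples
#' gas_displaceable_volume(device_preset("default"), back_pressure = 1)
gas_displaceable_volume <- function(config, back_pressure = 1,
                                    .validate = TRUE) {
  if (.validate) quiet_validate(config)
  if (!is.numeric(back_pressure) || length(back_pressure) != 1 ||
      back_pressure < 1) {
    abort("back_pressure must be a single value of at least 1 atm",
          class = "odrsim_domain_error")
  }
  v_res <- pi * config$gas_radius^2 * config$gas_height
  max(config$gas_initial_pressure * v_res / back_pressure - v_res, 0)
}

#' @export
print.device_config <- function(x, ...) {
  cat("<device_config>\n")
  cat(sprintf("  fluid piston: r %.3g cm, stroke %.3g cm | reservoir %.4g ml\n",
              x$fluid_piston_radius, x$fluid_piston_stroke,
              reservoir_capacity(x, .validate = FALSE)))
  cat(sprintf("  needle: %.3g mm long, %.3g mm ID, stow gap %.3g mm\n",
              x$needle_length, x$needle_inner_diameter, x$membrane_standoff))
  cat(sprintf("  gas charge: %.3g atm in %.4g cm^3\n",
              x$gas_initial_pressure, pi * x$gas_radius^2 * x$gas_height))
  cat(sprintf("  dosing: %g ml x %d, every %g s, trigger SpO2 <= %g%%\n",
              x$dose_volume, x$max_doses, x$redose_interval,
              x$spo2_threshold))
  invisible(x)
}
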