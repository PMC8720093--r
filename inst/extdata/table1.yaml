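# Published simulation and device parameters, kept verbatim (including the
# 5 atm gas charge, which cannot complete the full three-dose schedule and
# therefore raises a gas-budget warning on load).
device:
  fluid_piston_radius: 1.07        # cm
  fluid_piston_stroke: 1.1         # cm
  fluid_piston_initial_displacement: 0.01  # cm
  dead_volume: 1.0e-5              # cm^3
  fluid_initial_pressure: 1        # atm
  needle_piston_radius: 0.5        # cm
  needle_piston_stroke: 1.1        # cm
  needle_inner_diameter: 0.6       # mm
  needle_length: 8                 # mm
  chassis_mass: 500                # g
  spring_constant: 11              # N/m
  dashpot_coefficient: 11          # N s/m
  gas_initial_pressure: 5          # atm
  gas_radius: 0.3                  # cm
  gas_height: 0.9                  # cm
  fluid_viscosity: 0.658           # cSt
  fluid_density: 992.562           # kg/m^3
  wall_allowance_length: 0.86      # cm
  membrane_standoff: 3.0           # mm (stroke minus needle length)
  valve_conductance: 9.0e-14       # m^3/(Pa s)
  tissue_force_params:
    puncture_force: 1.6            # N
    tissue_stiffness: 220          # N/m
    tissue_damping: 2              # N s/m
    puncture_ramp: 0.2             # mm
  tissue_back_pressure: 0          # atm gauge
  dose_volume: 1                   # ml
  max_doses: 3
  redose_interval: 300             # s
  spo2_threshold: 90               # percent
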