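# Needle flow law, tissue-force law, phase dynamics and the full cycle.

default_cfg <- device_preset("default")

test_that("needle resistance matches the hand-evaluated Poiseuille law", {
  # mu = 0.658e-6 * 992.562 = 6.53106e-4 Pa.s;
  # R = 8 * mu * 0.008 / (pi * (3e-4)^4) = 1.64259e9, evaluated by hand
  expect_equal(needle_resistance(default_cfg), 1.64259e9, tolerance = 1e-4)
})

test_that("needle resistance scales as the inverse fourth power of radius", {
  base <- needle_resistance(default_cfg)
  doubled <- needle_resistance(device_config(needle_inner_diameter = 1.2))
  expect_equal(base / doubled, 16, tolerance = 1e-9)
  halved <- needle_resistance(device_config(needle_inner_diameter = 0.3))
  expect_equal(halved / base, 16, tolerance = 1e-9)
})

test_that("tissue force is gated at zero travel and monotone in velocity", {
  expect_equal(tissue_force(0, 0, default_cfg), 0)
  expect_error(tissue_force(-1e-3, 0, default_cfg),
               class = "odrsim_domain_error")
  # inside the membrane zone the puncture term dominates
  expect_gt(tissue_force(1e-3, 0, default_cfg), 1)
  # past the stow gap: elastic term at full stroke
  si <- as_si(default_cfg)
  expect_equal(tissue_force(si$stroke_n, 0, default_cfg),
               si$k_t * (si$stroke_n - si$standoff))
  v <- seq(0, 0.5, by = 0.1)
  f <- tissue_force(rep(5e-3, length(v)), v, default_cfg)
  expect_true(all(diff(f) >= 0))
})

test_that("derivatives vanish at equilibrium and with no pressure head", {
  st <- device_ready_state(default_cfg)
  d <- device_derivatives(st, default_cfg, valve_open = FALSE)
  expect_true(all(unlist(d) == 0))
  # INFUSING with fluid pressure at ambient: no flow
  si <- as_si(default_cfg)
  st$phase <- "INFUSING"
  st$x_needle <- si$stroke_n
  st$x_main <- 5e-3
  st$pv_lower <- 101325 * (si$A_f * st$x_main + si$V_dead)
  st$pv_reservoir <- 101325 * si$V_gas
  d <- device_derivatives(st, default_cfg, valve_open = FALSE)
  expect_equal(d$v_injected, 0)
  expect_equal(d$x_main, 0)
  st$x_main <- NaN
  expect_error(device_derivatives(st, default_cfg),
               class = "odrsim_integration_error")
})

test_that("infusion flow agrees with the quasi-static Boyle-law oracle", {
  # In the fast-valve limit the gas equilibrates: the pressure is the total
  # inventory divided by total volume (Boyle), and the flow is that head
  # over the hand-computed needle resistance.
  si <- as_si(default_cfg)
  r_hand <- 1.64259e9
  pv_tot <- si$P_gas0 * si$V_gas +
    si$P_fluid0 * (si$A_f * si$x0 + si$V_dead)
  xs <- seq(3e-3, 1.05e-2, length.out = 10)
  for (x in xs) {
    v_low <- si$A_f * x + si$V_dead
    p_eq <- pv_tot / (v_low + si$V_gas)       # Boyle-law pressure
    q_oracle <- (p_eq - 101325) / r_hand
    st <- device_ready_state(default_cfg)
    st$phase <- "INFUSING"
    st$x_needle <- si$stroke_n
    st$x_main <- x
    st$pv_lower <- p_eq * v_low
    st$pv_reservoir <- p_eq * si$V_gas
    d <- device_derivatives(st, default_cfg, valve_open = TRUE)
    expect_equal(d$v_injected, q_oracle, tolerance = 0.01)
    expect_equal(d$x_main, q_oracle / si$A_f, tolerance = 0.01)
  }
})

test_that("the default cycle meets the design milestones", {
  traj <- simulate_cycle(default_cfg)
  g <- glance(traj)
  expect_false(g$stalled)
  expect_true(g$completed)
  expect_lte(g$duration_s, 1.2)
  expect_equal(g$injected_ml, 1, tolerance = 0.01)
  expect_gte(g$peak_force_n, 1)
  # needle fully inserted (8 mm) at the INSERTING -> INFUSING transition
  ev <- tidy(traj)
  t_ins <- ev$t_s[ev$event == "insert_complete"]
  row <- traj[which.min(abs(traj$t_s - t_ins)), ]
  expect_equal(insertion_depth(row$x_needle_m, default_cfg), 8,
               tolerance = 1e-6)
})

test_that("trajectories conserve fluid volume and gas inventory", {
  traj <- simulate_cycle(default_cfg)
  si <- as_si(default_cfg)
  # gas: summed pressure-volume inventory constant to 0.1%
  pv_tot <- traj$pv_lower + traj$pv_reservoir
  expect_lt(max(abs(pv_tot - pv_tot[1])) / pv_tot[1], 1e-3)
  # fluid: main-piston sweep equals injected volume during INFUSING
  inf <- traj[traj$phase == "INFUSING", ]
  swept <- si$A_f * (inf$x_main_m - inf$x_main_m[1])
  injected <- (inf$v_injected_ml - inf$v_injected_ml[1]) * 1e-6
  expect_lt(max(abs(swept - injected)) / max(injected), 1e-3)
  # injected volume monotone, bounded by the reservoir
  expect_true(all(diff(traj$v_injected_ml) >= -1e-12))
  expect_lte(max(traj$v_injected_ml), reservoir_capacity(default_cfg))
  # no needle outflow before full insertion
  expect_true(all(traj$flow_m3s[traj$phase == "INSERTING"] == 0))
})

test_that("repeat doses continue from the terminal state without re-inserting", {
  t1 <- simulate_cycle(default_cfg)
  s1 <- attr(t1, "final_state")
  expect_equal(s1$phase, "DONE")
  t2 <- simulate_cycle(default_cfg, initial = s1)
  expect_true(all(t2$phase == "INFUSING"))
  g2 <- glance(t2)
  expect_true(g2$completed)
  expect_equal(g2$injected_ml, 1, tolerance = 0.01)
  t3 <- simulate_cycle(default_cfg, initial = attr(t2, "final_state"))
  g3 <- glance(t3)
  expect_true(g3$completed)
  # total delivered equals the full schedule
  expect_equal(attr(t3, "final_state")$v_injected * 1e6, 3,
               tolerance = 0.01)
})

test_that("a reduced valve conductance never shortens the cycle", {
  cvs <- 9e-14 * 2^seq(0, -2, length.out = 5)
  durations <- vapply(cvs, function(cv) {
    cfg <- device_config(valve_conductance = cv)
    glance(simulate_cycle(cfg))$duration_s
  }, numeric(1))
  expect_true(all(diff(durations) >= 0))
})

test_that("an undersized gas charge stalls the cycle with an explicit flag", {
  cfg <- suppressWarnings(device_preset("table1"))
  traj <- simulate_cycle(cfg, t_max = 100)
  expect_true(attr(traj, "stalled"))
  expect_false(attr(traj, "final_state")$phase == "DONE")
  expect_lt(glance(traj)$insertion_depth_mm, 8)
})

test_that("insertion depth maps piston travel through the stow gap", {
  si <- as_si(default_cfg)
  expect_equal(insertion_depth(0, default_cfg), 0)
  expect_equal(insertion_depth(si$stroke_n, default_cfg), 8)
  expect_equal(insertion_depth(si$standoff / 2, default_cfg), 0)
  # depth never exceeds the needle length over the admissible stroke
  xs <- seq(0, si$stroke_n, length.out = 50)
  expect_true(all(insertion_depth(xs, default_cfg) <=
                    default_cfg$needle_length + 1e-9))
})
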