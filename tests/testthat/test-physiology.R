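# Dissociation curve, trace generation and the antidote recovery model.

test_that("the dissociation curve reproduces the 60 mmHg / 90% anchor", {
  # 1 / (23400 / (60^3 + 150*60) + 1), evaluated by hand
  expect_equal(severinghaus_sao2(60), 0.9057971, tolerance = 1e-6)
  expect_equal(inverse_severinghaus(0.90), 60, tolerance = 3 / 60)
  expect_gt(severinghaus_sao2(600), 0.999)
  grid <- seq(10, 600, length.out = 50)
  expect_true(all(diff(severinghaus_sao2(grid)) > 0))
  expect_error(severinghaus_sao2(0), class = "odrsim_domain_error")
  expect_error(inverse_severinghaus(1), class = "odrsim_domain_error")
})

test_that("the inverse round-trips to below 1e-9 across the range", {
  s <- seq(0.05, 0.999, length.out = 100)
  p <- inverse_severinghaus(s)
  expect_true(all(diff(p) > 0))
  expect_lt(max(abs(severinghaus_sao2(p) - s)), 1e-9)
  expect_equal(inverse_severinghaus(severinghaus_sao2(100)), 100,
               tolerance = 1e-9)
})

test_that("a noise-free baseline trace is constant at its mean", {
  p <- scenario_params(baseline_noise_sd = 0, diurnal_amplitude = 0)
  tr <- generate_spo2_trace(p, duration = 100, rate = 1, seed = 1)
  expect_true(all(tr$spo2_pct == 95))
  expect_equal(nrow(tr), 101)
})

test_that("the desaturation ramp crosses the threshold on schedule", {
  # 5% drop at 2%/min takes 150 s: onset 600 s puts the first <= 90 sample
  # at 750 s
  p <- scenario_params(baseline_noise_sd = 0, diurnal_amplitude = 0,
                       overdose_onset = 600, desaturation_rate = 2,
                       floor = 80)
  tr <- generate_spo2_trace(p, duration = 1200, rate = 1, seed = 1)
  first_low <- min(tr$t_s[tr$spo2_pct <= 90])
  expect_lte(abs(first_low - 750), 1)
  expect_equal(min(tr$spo2_pct), 80)
  # the exponential variant starts at the same slope but approaches the
  # floor smoothly
  pe <- scenario_params(baseline_noise_sd = 0, diurnal_amplitude = 0,
                        overdose_onset = 600, desaturation_rate = 2,
                        floor = 80, desaturation_shape = "exponential")
  tre <- generate_spo2_trace(pe, duration = 7200, rate = 1, seed = 1)
  expect_gt(min(tre$spo2_pct), 80)
  expect_lt(min(tre$spo2_pct), 81)
})

test_that("traces stay within physical bounds and reproduce under a seed", {
  p <- scenario_params(baseline_noise_sd = 2, overdose_onset = 300,
                       desaturation_rate = 10, floor = 0.5)
  a <- generate_spo2_trace(p, duration = 900, rate = 2, seed = 42)
  b <- generate_spo2_trace(p, duration = 900, rate = 2, seed = 42)
  c <- generate_spo2_trace(p, duration = 900, rate = 2, seed = 43)
  expect_identical(a$spo2_pct, b$spo2_pct)
  expect_false(identical(a$spo2_pct, c$spo2_pct))
  expect_true(all(a$spo2_pct >= 0 & a$spo2_pct <= 100))
  expect_true(all(diff(a$t_s) > 0))
})

test_that("parameter validation guards the physiologic ranges", {
  expect_error(scenario_params(baseline_mean = 88),
               class = "odrsim_param_error")
  expect_error(scenario_params(floor = -1), class = "odrsim_param_error")
  expect_error(scenario_params(nalmefene_half_life = 0),
               class = "odrsim_param_error")
})

test_that("bolus antidote concentration halves every elimination half-life", {
  p <- scenario_params(absorption_rate = Inf, nalmefene_half_life = 8)
  h <- 3600
  expect_equal(pk_concentration(8 * h, 0, p), 0.5, tolerance = 1e-12)
  expect_equal(pk_concentration(16 * h, 0, p), 0.25, tolerance = 1e-12)
  # superposition over two doses
  expect_equal(pk_concentration(8 * h, c(0, 8 * h), p), 1.5,
               tolerance = 1e-12)
  # first-order absorption starts from zero and stays non-negative
  pa <- scenario_params(absorption_rate = 20)
  t <- seq(0, 7200, by = 60)
  conc <- pk_concentration(t, 0, pa)
  expect_equal(conc[1], 0)
  expect_true(all(conc >= 0))
})

test_that("dose response leaves the trace unchanged with no doses", {
  p <- scenario_params(overdose_onset = 300, pk_feedback = TRUE)
  tr <- generate_spo2_trace(p, duration = 900, rate = 1, seed = 5)
  expect_identical(apply_dose_response(tr, numeric(), p), tr)
  expect_error(apply_dose_response(tr, 1500, p),
               class = "odrsim_domain_error")
  # zero-effect recovery also leaves the trace unchanged
  p0 <- scenario_params(overdose_onset = 300, pk_feedback = TRUE,
                        recovery_rate = 0)
  tr0 <- generate_spo2_trace(p0, duration = 900, rate = 1, seed = 5)
  out0 <- apply_dose_response(tr0, 400, p0)
  expect_equal(out0$spo2_pct, tr0$spo2_pct, tolerance = 1e-12)
})

test_that("a strong first dose restores saturation before the recheck", {
  cfg <- device_preset("default")
  p <- scenario_preset("overdose-recovery")
  tr <- generate_spo2_trace(p, duration = 1500, rate = 1, seed = 3)
  res <- run_closed_loop(tr, cfg, simulate_device = FALSE)
  expect_equal(sum(res$log$kind == "DOSE"), 1)
  expect_equal(sum(res$log$kind == "ALERT"), 1)
  t_dose <- res$log$t_s[res$log$kind == "DOSE"][1]
  at_recheck <- res$trace$spo2_pct[res$trace$t_s >= t_dose + 300][1]
  expect_gt(at_recheck, 90)
})

test_that("zero-effect feedback reduces to the open-loop dose schedule", {
  cfg <- device_preset("default")
  p <- scenario_params(overdose_onset = 60, desaturation_rate = 10,
                       floor = 80, pk_feedback = TRUE, recovery_rate = 0,
                       baseline_noise_sd = 0, diurnal_amplitude = 0)
  tr <- generate_spo2_trace(p, duration = 1200, rate = 1, seed = 8)
  res <- run_closed_loop(tr, cfg, simulate_device = FALSE)
  expect_equal(sum(res$log$kind == "DOSE"), cfg$max_doses)
})
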