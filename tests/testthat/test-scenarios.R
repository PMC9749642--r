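test_that("scenario specs enforce the baseline and ramp conventions", {
  expect_error(scenario_spec("S1", patient_ratio_ramp = 0.01), "baseline")
  expect_error(scenario_spec("S9"), "unknown scenario")
  s2 <- scenario_spec("S2", patient_ratio_ramp = 0.002, los_ramp = 0.05)
  expect_s3_class(s2, "scenario_spec")
})

test_that("applying the baseline scenario leaves the config identical", {
  cfg <- fixture_config()
  expect_identical(apply_scenario(cfg, "S1"), cfg)
  expect_error(apply_scenario(cfg, "S7"), "unknown scenario")
})

test_that("scenario ramps act only after the intervention start", {
  cfg <- fixture_config()
  r1 <- fixture_run()
  r2 <- simulate_config(cfg, "S2")
  ratio <- run_variable(r2, "patient_to_population_ratio")
  tt <- r2$times
  expect_true(all(ratio[tt <= 2020] == 0.129))
  post <- ratio[tt > 2020]
  expect_true(all(diff(post) > 0))
  # ramp slope: +0.002 per year
  expect_equal(ratio[tt == 2030], 0.129 + 0.002 * 10, tolerance = 1e-12)
})

test_that("a negative travelers ramp weakly lowers the travel inflow", {
  cfg <- fixture_config()
  s <- scenario_spec("S4", travelers_ratio_ramp = -1.5)
  r_base <- fixture_run()
  r_neg <- simulate_config(cfg, s)
  expect_true(all(run_variable(r_neg, "flow_of_travelers") <=
                    run_variable(r_base, "flow_of_travelers") + 1e-9))
  # clamped at zero even for extreme ramps over long horizons
  s_big <- scenario_spec("S4", travelers_ratio_ramp = -20)
  r_big <- simulate_config(cfg, s_big)
  expect_true(all(run_variable(r_big, "travelers_to_specialists_ratio") >= 0))
})

test_that("policy specs enforce the lever conventions", {
  expect_error(policy_spec("P1", bed_addition = 1), "no intervention")
  expect_error(policy_spec("P2", home_care_addition = 5), "beds only")
  expect_error(policy_spec("P3", bed_addition = 5), "home care only")
  expect_error(policy_spec("P4", bed_addition = -1), "nonnegative")
  expect_identical(apply_policy(fixture_config(), "P1"), fixture_config())
})

test_that("with inert feedback a bed policy accumulates exactly linearly", {
  cfg <- inert_config()
  pol <- policy_spec("P2", bed_addition = 100, start_year = 2020)
  run <- simulate_config(cfg, "S1", pol)
  beds <- run_variable(run, "number_of_bed")
  tt <- run$times
  expect_true(all(beds[tt <= 2020] == 3560))
  expect_equal(beds[tt == 2030], 3560 + 100 * 10, tolerance = 1e-12)
  expect_equal(beds[length(beds)], 3560 + 100 * 15, tolerance = 1e-12)
})

test_that("interventions weakly raise the end-state capacities", {
  cfg <- fixture_config()
  base <- fixture_run()
  pol <- policy_spec("P4", bed_addition = 40, home_care_addition = 5000)
  r <- simulate_config(cfg, "S1", pol)
  n <- nrow(r$values)
  expect_gte(r$values[n, "number_of_bed"],
             base$values[n, "number_of_bed"])
  expect_gte(r$values[n, "capacity_of_home_care_services"],
             base$values[n, "capacity_of_home_care_services"])
})

test_that("first_shortage_time reads the earliest crossing off the grid", {
  m <- sd_model(
    sd_aux("shortage_bed_day", "IF_THEN_ELSE(TIME >= 2015 + 26/12, 1, 0)"))
  run <- sd_simulate(m, simulation_settings(2015, 2020, dt = 1 / 12))
  expect_equal(first_shortage_time(run), 26 / 12, tolerance = 1e-9)

  none <- sd_model(sd_aux("shortage_bed_day", "0 * TIME"))
  r0 <- sd_simulate(none, simulation_settings(2015, 2020, dt = 1 / 12))
  expect_true(is.na(first_shortage_time(r0)))
  expect_error(first_shortage_time(
    sd_simulate(sd_model(sd_param("a", 1)),
                simulation_settings(0, 1, dt = 1))),
    "shortage_bed_day")
})

test_that("the bisection solver matches an exhaustive grid-search oracle", {
  cfg <- toy_shortage_config()
  base_peak <- peak_shortage(simulate_config(cfg))
  expect_gt(base_peak, 0)

  p2 <- solve_min_intervention(cfg, "P2")
  expect_lte(attr(p2, "peak_shortage"), 1)

  # oracle: scan bed additions at 0.01 beds/year resolution
  grid <- seq(0, ceiling(p2$bed_addition) + 1, by = 0.01)
  peaks <- vapply(grid, function(b) {
    pol <- policy_spec("P2", bed_addition = b, start_year = 2020)
    peak_shortage(simulate_config(cfg, "S1", pol))
  }, 0)
  b_star <- grid[which(peaks <= 1)[1]]
  expect_lt(abs(p2$bed_addition - b_star), 0.01 + 1e-9)
})

test_that("solved interventions are sound, minimal and zero when unneeded", {
  expect_identical(
    solve_min_intervention(inert_config(), "P2")$bed_addition, 0)

  for (pid in c("P2", "P3")) {
    cfg <- if (pid == "P2") toy_shortage_config() else toy_homecare_config()
    pol <- solve_min_intervention(cfg, pid)
    peak_fn <- function(b, h) {
      p <- policy_spec("P4", bed_addition = b, home_care_addition = h,
                       start_year = 2020)
      peak_shortage(simulate_config(cfg, "S1", p))
    }
    expect_lte(peak_fn(pol$bed_addition, pol$home_care_addition), 1)
    # minimality: stepping the binding lever down by 10 tol-equivalents
    # (local slope estimate) re-opens the shortage
    lever <- max(pol$bed_addition, pol$home_care_addition)
    eps <- lever * 1e-3
    if (pid == "P2") {
      slope <- (peak_fn(pol$bed_addition - eps, 0) -
                  peak_fn(pol$bed_addition, 0)) / eps
      delta <- 10 * 1 / slope
      expect_gt(peak_fn(pol$bed_addition - delta, 0), 1)
    } else {
      slope <- (peak_fn(0, pol$home_care_addition - eps) -
                  peak_fn(0, pol$home_care_addition)) / eps
      delta <- 10 * 1 / slope
      expect_gt(peak_fn(0, pol$home_care_addition - delta), 1)
    }
  }

  cfg <- toy_homecare_config() # P4 needs a live home-care channel
  p2 <- solve_min_intervention(cfg, "P2")
  p4 <- solve_min_intervention(cfg, "P4")
  expect_lte(p4$bed_addition, p2$bed_addition + 1e-6)
})

test_that("the sweep is complete, consistent and deterministic on a quiet config", {
  cfg <- quiet_config() # no shortage anywhere: solves return zero levers
  sw <- scenario_policy_sweep(cfg)
  expect_equal(nrow(sw), 16)
  expect_identical(sw$scenario, rep(c("S1", "S2", "S3", "S4"), each = 4))
  expect_identical(sw$policy, rep(c("P1", "P2", "P3", "P4"), times = 4))
  expect_true(all(sw$bed_addition == 0))

  direct <- simulate_config(cfg, "S2")
  n <- nrow(direct$values)
  row <- sw[sw$scenario == "S2" & sw$policy == "P1", ]
  expect_identical(row$end_beds, unname(direct$values[n, "number_of_bed"]))

  sw2 <- scenario_policy_sweep(cfg)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
})
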