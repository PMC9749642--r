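test_that("the assembled bed model is runnable and statically correct", {
  cfg <- fixture_config()
  m <- config_model(cfg)
  expect_length(validate_model(m)$defects, 0)

  run <- fixture_run()
  expect_equal(unname(run$values[1, "total_bed_day"]), 3560 * 365)
  expect_equal(unname(run$values[1, "specialist_to_bed_ratio"]),
               690 / 3560, tolerance = 1e-12)
  expect_equal(unname(run$values[1, "population"]), 1557600)
})

test_that("constructor invariants reject out-of-range inputs", {
  expect_error(bed_parameters(60, 3.5, optimal_occupancy = 1.2), "0, 1")
  expect_error(bed_parameters(-1, 3.5), "nonnegative")
  expect_error(bed_parameters(60, 3.5, days_per_year = 360), "365")
  expect_error(bed_initial_stocks(population = -5), "nonnegative")
  up <- lookup_table(c(0, 1), c(0, 0.1))
  down <- lookup_table(c(0, 1), c(0.1, 0))
  one <- lookup_table(c(0, 1), c(1, 1))
  expect_error(rate_effect_tables(down, down, down, one), "non-decreasing")
  expect_error(rate_effect_tables(up, up, down, one), "non-increasing")
  expect_error(rate_effect_tables(up, down, down, down), "F4\\(0\\)")
  expect_s3_class(rate_effect_tables(up, down, down, one),
                  "rate_effect_tables")
})

test_that("the demand block reproduces the occupancy-cap arithmetic", {
  params <- bed_parameters(travelers_to_specialists_ratio = 0,
                           base_length_of_stay = 3.5)
  d <- eval_demand_block(1557600, 690, 3560, 3.5, params)
  expect_equal(d$total_patient, 200930.4) # residents only, ratio 0.129

  params60 <- bed_parameters(60, 3.5)
  # demand above the cap: occupancy pinned at 85%, excess is shortage
  los <- 1200000 / eval_demand_block(1557600, 690, 3560, 1, params60)$total_patient
  d <- eval_demand_block(1557600, 690, 3560, los, params60)
  expect_equal(d$total_bed_day_required, 1200000, tolerance = 1e-9)
  expect_equal(d$bed_occupancy_day, 0.85 * 1299400) # 1,104,490
  expect_equal(d$bed_occupancy_rate, 0.85)
  expect_equal(d$shortage_bed_day, 1200000 - 1104490, tolerance = 1e-6)

  # demand below the cap: occupancy follows demand, no shortage
  los <- 1000000 / eval_demand_block(1557600, 690, 3560, 1, params60)$total_patient
  d <- eval_demand_block(1557600, 690, 3560, los, params60)
  expect_equal(d$bed_occupancy_day, 1000000, tolerance = 1e-9)
  expect_equal(d$bed_occupancy_rate, 1000000 / 1299400, tolerance = 1e-12)
  expect_identical(d$shortage_bed_day, 0)
})

test_that("the growth block forms fractional-rate inflows from the lookups", {
  params <- bed_parameters(60, 3.5)
  stocks <- list(number_of_bed = 3560,
                 number_of_specialist_physicians = 690,
                 capacity_of_home_care_services = 76650)
  demand <- eval_demand_block(1557600, 690, 3560, 3.5, params)

  inert <- rate_effect_tables(
    F1 = lookup_table(c(0, 1), c(0, 0)),
    F2 = lookup_table(c(0, 1), c(0, 0)),
    F3 = lookup_table(c(0, 1), c(0, 0)),
    F4 = lookup_table(c(0, 1), c(1, 1)))
  g <- eval_growth_block(stocks, demand, inert, params)
  expect_identical(g$bed_increase_rate, 0)
  expect_identical(g$specialist_increase_rate, 0)
  expect_identical(g$home_care_increase_rate, 0)
  expect_equal(g$length_of_stay, 3.5)

  const3 <- inert
  const3$F3 <- lookup_table(c(0, 1), c(0.02, 0.02), "F3")
  g <- eval_growth_block(stocks, demand, const3, params)
  expect_equal(g$bed_increase_rate, 71.2) # 3560 * 0.02
})

test_that("home-care growth responds monotonically to occupancy", {
  params <- bed_parameters(60, 3.5)
  stocks <- list(number_of_bed = 3560,
                 number_of_specialist_physicians = 690,
                 capacity_of_home_care_services = 76650)
  demand <- eval_demand_block(1557600, 690, 3560, 3.5, params)
  set.seed(42)
  for (i in 1:100) {
    F1 <- rand_monotone_table(sample(3:6, 1), c(0, 1), "inc", name = "F1")
    lo <- demand; lo$bed_occupancy_rate <- 0.6
    hi <- demand; hi$bed_occupancy_rate <- 0.9
    tabs <- rate_effect_tables(
      F1 = F1,
      F2 = lookup_table(c(0, 1), c(0, 0)),
      F3 = lookup_table(c(0, 1), c(0, 0)),
      F4 = lookup_table(c(0, 1), c(1, 1)))
    g_lo <- eval_growth_block(stocks, lo, tabs, params)
    g_hi <- eval_growth_block(stocks, hi, tabs, params)
    # oracle: direct lookup evaluation at the two occupancy levels
    expect_identical(g_lo$home_care_increase_rate,
                     76650 * lookup_eval(F1, 0.6))
    expect_gte(g_hi$home_care_increase_rate, g_lo$home_care_increase_rate)
  }
})

test_that("occupancy stays capped and shortage is its complement on runs", {
  run <- fixture_run()
  occ <- run_variable(run, "bed_occupancy_rate")
  sh <- run_variable(run, "shortage_bed_day")
  expect_true(all(occ <= 0.85 + 1e-9))
  expect_true(all(sh >= 0))
  expect_true(all(abs(occ[sh > 0] - 0.85) <= 1e-9))
  expect_true(all(occ[sh == 0] <= 0.85 + 1e-9))
})
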