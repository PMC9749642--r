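test_that("fit metrics behave like MAPE and RMSE should", {
  cfg <- fixture_config()
  run <- sd_simulate(config_model(cfg), simulation_settings(
    2015, 2019, dt = cfg$simulation$dt, saveper = 1))
  hist0 <- gen_history(cfg, synthesis_settings(noise_sd = 0))
  fit <- compare_to_history(run, hist0)
  expect_true(all(fit$mape == 0))
  expect_true(all(fit$rmse == 0))
  expect_identical(attr(fit, "worst_mape"), 0)

  # a constant x1.10 bias is exactly 10% MAPE on that variable
  hist_b <- hist0
  hist_b$observed$number_of_bed <- hist0$observed$number_of_bed * 1.10
  fit <- compare_to_history(run, hist_b)
  expect_equal(fit$mape[fit$variable == "number_of_bed"],
               100 * (1.10 - 1) / 1.10, tolerance = 1e-9)

  # scale invariance: scaling a variable and its observations together
  # leaves MAPE unchanged (RMSE scales)
  m <- sd_model(sd_param("v", 10), sd_aux("w", "v * 3"))
  r <- sd_simulate(m, simulation_settings(2015, 2019, dt = 1))
  h1 <- historical_series(2015:2019, data.frame(w = rep(33, 5)))
  h2 <- historical_series(2015:2019, data.frame(w = rep(33 * 100, 5)))
  m2 <- sd_model(sd_param("v", 10), sd_aux("w", "v * 300"))
  r2 <- sd_simulate(m2, simulation_settings(2015, 2019, dt = 1))
  expect_equal(compare_to_history(r, h1)$mape,
               compare_to_history(r2, h2)$mape, tolerance = 1e-12)

  # zero observations drop out of MAPE with a warning
  hz <- historical_series(2015:2019, data.frame(w = c(0, 33, 33, 33, 33)))
  expect_warning(fz <- compare_to_history(r, hz), "zero observation")
  expect_equal(fz$mape, 100 * mean(abs(30 - 33) / 33), tolerance = 1e-12)
})

test_that("noisy synthetic history yields a commensurately small MAPE", {
  cfg <- fixture_config()
  run <- sd_simulate(config_model(cfg), simulation_settings(
    2015, 2019, dt = cfg$simulation$dt, saveper = 1))
  hist <- gen_history(cfg, synthesis_settings(seed = 99, noise_sd = 0.05))
  fit <- compare_to_history(run, hist)
  expect_true(all(fit$mape > 0))
  expect_lt(attr(fit, "worst_mape"), 15) # 3 x the 5% noise scale
})

test_that("extreme conditions produce the expected marginal behaviour", {
  rep <- extreme_condition_suite(fixture_config())
  expect_setequal(rep$check, c("zero_population", "zero_demand",
                               "abundant_beds", "zero_length_of_stay"))
  expect_true(all(rep$pass))
})

test_that("the model holds equilibrium when all drivers are switched off", {
  cfg <- fixture_config()
  rep <- equilibrium_test(cfg)
  expect_true(all(rep$pass))
  expect_lt(attr(rep, "max_drift"), 1e-9)

  # identical at coarse and fine steps: the derivative is exactly zero
  rep1 <- equilibrium_test(config_modify(cfg, simulation = list(
    dt = 1, saveper = 1)))
  expect_true(all(rep1$pass))

  # a perturbed lookup breaks equilibrium for its own stock only
  lk <- bedflow:::inert_lookups(cfg$lookups)
  lk$F3 <- lookup_table(range(cfg$lookups$F3$x), c(0.01, 0.01), "F3")
  pert <- config_modify(cfg, parameters = list(growth_proportion = 0),
                        lookups = lk)
  run <- simulate_config(pert)
  beds <- run_variable(run, "number_of_bed")
  expect_gt(beds[length(beds)], beds[1])
  pop <- run_variable(run, "population")
  expect_equal(max(abs(pop - pop[1])), 0)
})

test_that("validity checks never mutate the input configuration", {
  cfg <- fixture_config()
  before <- config_digest(cfg)
  invisible(extreme_condition_suite(cfg))
  invisible(equilibrium_test(cfg))
  expect_identical(config_digest(cfg), before)
})

test_that("a generating lookup table is recovered from noiseless history", {
  base <- inert_config()
  lk <- base$lookups
  gen_F3 <- lookup_table(c(0.0125, 0.0135, 0.0146),
                         c(0.012, 0.007, 0.004), "F3")
  lk$F3 <- gen_F3
  cfg <- config_modify(base,
                       lookups = do.call(rate_effect_tables,
                                         lk[c("F1", "F2", "F3", "F4")]),
                       simulation = list(dt = 1 / 4, saveper = 1 / 4))
  run <- simulate_config(cfg)
  yearly <- seq(1, length(run$times), by = 4)
  hist <- historical_series(
    run$times[yearly],
    data.frame(number_of_bed = run_variable(run, "number_of_bed")[yearly]))
  fit <- recover_lookup_slopes(cfg, hist, "F3",
                               y_init = c(0.02, 0.01, 0.005))
  expect_true(all(abs(fit$table$y - gen_F3$y) / gen_F3$y < 0.01))
  expect_false(any(fit$underdetermined))
})

test_that("an inert loop is reported as under-determined, not fitted", {
  cfg <- config_modify(inert_config(),
                       simulation = list(dt = 1 / 4, saveper = 1 / 4))
  run <- simulate_config(cfg)
  yearly <- seq(1, length(run$times), by = 4)
  # the observed variable does not respond to the target table at all
  hist <- historical_series(
    run$times[yearly],
    data.frame(population = run_variable(run, "population")[yearly]))
  expect_warning(
    fit <- recover_lookup_slopes(cfg, hist, "F3", y_init = c(0, 0)),
    "insensitive")
  expect_true(all(fit$underdetermined))
})
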