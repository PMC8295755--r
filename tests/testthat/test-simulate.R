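test_that("configuration validation enforces the generative contract", {
  expect_error(simulation_config(residual_sd = -1), "residual_sd")
  expect_error(simulation_config(event_years = 1950, years = 1970:2010),
               "within years")
  expect_error(simulation_config(precip_shape = rep(-1, 12)), "positive")
  expect_equal(true_repeatability(simulation_config(
    tree_sensitivity_sd = 0.1, residual_sd = 0.15)),
    0.01 / 0.0325)
  expect_equal(true_repeatability(simulation_config(
    tree_sensitivity_sd = 0, residual_sd = 0)), 0)
})

test_that("all three generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 77, n_provenances = 3, trees_per_provenance = 4)
  expect_identical(simulate_precip(cfg), simulate_precip(cfg))
  expect_identical(simulate_response_table(cfg), simulate_response_table(cfg))
  expect_identical(simulate_ring_widths(cfg), simulate_ring_widths(cfg))
  # and a different seed changes the draw
  cfg2 <- simulation_config(seed = 78, n_provenances = 3, trees_per_provenance = 4)
  expect_false(identical(simulate_precip(cfg)$precip_mm,
                         simulate_precip(cfg2)$precip_mm))
})

test_that("simulated precipitation matches its gamma parameters", {
  cfg <- simulation_config(seed = 5, years = 1971:2010)
  st <- simulate_precip(cfg)
  expect_true(all(st$precip_mm >= 0))
  expect_equal(length(unique(st$station_id)), 4L)
  one <- st[st$station_id == "ST01" & !(st$year %in% cfg$event_years), ]
  for (cm in c(1, 7)) {
    v <- one$precip_mm[one$month == cm]
    mu <- cfg$precip_shape[cm] * cfg$precip_scale[cm]
    se <- sqrt(cfg$precip_shape[cm]) * cfg$precip_scale[cm] / sqrt(length(v))
    expect_lt(abs(mean(v) - mu), 3 * se)
  }
  # embedded dry spells depress the event-year growing season
  spell <- st$precip_mm[st$year %in% cfg$event_years & st$month %in% 4:9]
  usual <- st$precip_mm[!(st$year %in% cfg$event_years) & st$month %in% 4:9]
  expect_lt(mean(spell), 0.5 * mean(usual))
})

test_that("ring widths follow the age trend exactly in the noiseless limit", {
  cfg <- simulation_config(seed = 3, n_provenances = 2, trees_per_provenance = 2,
                           provenance_effect_sd = 0, tree_sensitivity_sd = 0,
                           residual_sd = 0, tree_baseline_sd = 0,
                           growth_noise_sd = 0, core_noise_sd = 0,
                           event_years = integer(0))
  sim <- simulate_ring_widths(cfg)
  s <- tree_series(sim$collection, sim$collection$tree_id[1])
  age <- seq_along(cfg$years) - 1
  expect_equal(s$width_mm,
               cfg$age_scale_mm * exp(-cfg$age_decay * age) + cfg$age_floor_mm)
})

test_that("event multipliers below one depress drought-year growth", {
  cfg <- simulation_config(seed = 31, n_provenances = 3, trees_per_provenance = 5)
  cfg0 <- cfg
  cfg0$event_years <- integer(0)
  with_ev <- simulate_ring_widths(cfg)
  without <- simulate_ring_widths(validate_sim_config(unclass(cfg0)))
  # outside event years the two runs are the same seeded trial
  non_ev <- !(with_ev$collection$year %in% cfg$event_years)
  expect_equal(with_ev$collection$width_mm[non_ev],
               without$collection$width_mm[non_ev])
  for (id in unique(with_ev$collection$tree_id)) {
    mult <- with_ev$truth$event_multipliers[[id]]
    for (ev in cfg$event_years) {
      w1 <- with_ev$collection$width_mm[with_ev$collection$year == ev &
                                          with_ev$collection$tree_id == id]
      w0 <- without$collection$width_mm[without$collection$year == ev &
                                          without$collection$tree_id == id]
      if (mult[[as.character(ev)]] < 1) expect_lt(w1, w0)
    }
  }
})

test_that("the closed-loop pipeline recovers the configured repeatability", {
  r_true <- 0.4
  resid_sd <- 0.15
  cfg <- simulation_config(seed = 41, n_provenances = 6,
                           trees_per_provenance = 60,
                           tree_sensitivity_sd = sqrt(r_true * resid_sd^2 /
                                                        (1 - r_true)),
                           residual_sd = resid_sd, growth_noise_sd = 0.01,
                           core_noise_sd = 0.01)
  sim <- simulate_ring_widths(cfg)
  tab <- compute_response_table(sim$collection, cfg$event_years)
  d <- defined_records(tab, "Res")
  r <- repeatability(reml_varcomp(standardize_log(d$value), d$tree_id))
  # growth noise inside the 9-year window adds a little residual variance,
  # so the estimate sits near, mostly slightly below, the configured value
  expect_lt(abs(r$r - r_true), 0.1)
})

test_that("higher tree-level sensitivity variance raises estimated r", {
  rs <- vapply(c(0.05, 0.3, 0.6), function(r_true) {
    resid_sd <- 0.15
    cfg <- simulation_config(seed = 52, n_provenances = 6,
                             trees_per_provenance = 50,
                             tree_sensitivity_sd = sqrt(r_true * resid_sd^2 /
                                                          (1 - r_true)),
                             residual_sd = resid_sd)
    sim <- simulate_response_table(cfg)
    d <- defined_records(sim$table, "Res")
    repeatability(reml_varcomp(standardize_log(d$value), d$tree_id))$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})
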