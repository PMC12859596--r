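test_that("reference rates match the pooled-ratio oracle on the toy panel", {
  rates <- compute_reference_rates(toy_panel())
  # direct arithmetic: young 3/400, old 7/600
  expect_equal(rates$rate[rates$age_band == "young"], 3 / 400)
  expect_equal(rates$rate[rates$age_band == "old"], 7 / 600)
})

test_that("expected counts match the toy oracle and conserve the total", {
  panel <- toy_panel()
  rates <- compute_reference_rates(panel)
  e <- compute_expected_counts(panel, rates)
  e1 <- 100 * 3 / 400 + 200 * 7 / 600
  e2 <- 300 * 3 / 400 + 400 * 7 / 600
  expect_equal(e$expected[e$area_id == "a1"], e1, tolerance = 1e-12)
  expect_equal(e$expected[e$area_id == "a2"], e2, tolerance = 1e-12)
  expect_equal(e1, 3.083333, tolerance = 1e-6)
  expect_equal(e2, 6.916667, tolerance = 1e-6)
  expect_equal(sum(e$expected), sum(panel$deaths), tolerance = 1e-12)
})

test_that("degenerate panels behave as stated", {
  panel <- toy_panel()
  zero <- panel
  zero$deaths <- 0L
  rates0 <- compute_reference_rates(stratified_panel(zero))
  expect_true(all(rates0$rate == 0))
  e0 <- compute_expected_counts(panel, rates0)
  expect_true(all(e0$expected == 0))

  # duplicating every area leaves rates unchanged (ratio invariance)
  dup <- as.data.frame(panel)
  dup2 <- dup
  dup2$area_id <- paste0(dup2$area_id, "x")
  rates_dup <- compute_reference_rates(stratified_panel(rbind(dup, dup2)))
  expect_equal(rates_dup$rate, compute_reference_rates(panel)$rate)
})

test_that("conservation and scale equivariance hold on simulated panels", {
  g <- make_lattice_graph(4, 4)
  x <- simulate_covariates(g, K = 3, spatial_corr = 0.5, seed = 2)
  for (s in 1:3) {
    pars <- random_params(g, 5, K = 3, seed = s)
    sim <- simulate_dataset(g, x, pars, n_years = 5, seed = 10 + s)
    rates <- compute_reference_rates(sim$panel)
    e <- compute_expected_counts(sim$panel, rates)
    expect_lt(abs(sum(e$expected) - sum(sim$panel$deaths)) /
                max(1, sum(sim$panel$deaths)), 1e-9)
    # scaling populations by c scales E by c at fixed rates
    scaled <- as.data.frame(sim$panel)
    scaled$population <- scaled$population * 2.5
    e2 <- compute_expected_counts(stratified_panel(scaled), rates)
    expect_equal(e2$expected, 2.5 * e$expected, tolerance = 1e-12)
  }
})

test_that("standardisation errors name the offending stratum", {
  panel <- as.data.frame(toy_panel())
  panel$population[panel$age_band == "young"] <- 0
  panel$deaths[panel$age_band == "young"] <- 0L
  expect_error(compute_reference_rates(stratified_panel(panel)),
               "young.*zero pooled population")
  rates <- compute_reference_rates(toy_panel())
  expect_error(compute_expected_counts(toy_panel(),
                                       rates[rates$age_band != "old", ]),
               "old")
})
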