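test_that("stratum allocation conserves every area-year total exactly", {
  g <- make_lattice_graph(4, 4)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0.5, seed = 1)
  pars <- random_params(g, 4, K = 2, seed = 2)
  sim <- simulate_dataset(g, x, pars, n_years = 4, seed = 3)
  tot <- panel_totals(sim$panel)
  y <- matrix(tot$deaths, nrow = g$n_areas, ncol = 4, byrow = TRUE)
  expect_equal(y, unname(sim$truth$totals))
  expect_equal(sum(sim$panel$deaths), sum(sim$truth$totals))
})

test_that("the hurdle gate controls zeros as specified", {
  g <- make_lattice_graph(5, 5)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0, seed = 1)
  pars <- zero_params(g$n_areas, 6, 2)
  closed <- simulate_dataset(g, x, pars, n_years = 6, seed = 4, pi_fixed = 0)
  expect_true(all(closed$panel$deaths == 0L))
  open <- simulate_dataset(g, x, pars, n_years = 6, seed = 4, pi_fixed = 1)
  expect_true(all(open$truth$totals >= 1L))
})

test_that("with the gate open, totals match the analytic ZTP mean inflation", {
  # ~10^4 replicate area-years with all effects zero
  g <- make_lattice_graph(40, 25)
  x <- simulate_covariates(g, K = 1, spatial_corr = 0, seed = 5)
  pars <- zero_params(g$n_areas, 10, 1)
  sim <- simulate_dataset(g, x, pars, n_years = 10, seed = 6, pi_fixed = 1)
  mu <- sim$truth$E
  m_th <- ztpois_mean(mu)                       # analytic ZTP mean oracle
  v_th <- mu * (1 + mu) / (1 - exp(-mu)) - m_th^2
  expect_lt(abs(sum(sim$truth$totals) - sum(m_th)), 3 * sqrt(sum(v_th)))
})

test_that("the empirical zero fraction matches 1 - pi", {
  g <- make_lattice_graph(40, 25)
  x <- simulate_covariates(g, K = 1, spatial_corr = 0, seed = 5)
  pars <- zero_params(g$n_areas, 10, 1, alpha_b = 0.8)
  sim <- simulate_dataset(g, x, pars, n_years = 10, seed = 7)
  p <- plogis(0.8)
  N <- length(sim$truth$totals)
  expect_lt(abs(mean(sim$truth$totals == 0) - (1 - p)),
            3 * sqrt(p * (1 - p) / N))
})

test_that("simulation is a pure function of its seed", {
  g <- make_lattice_graph(3, 3)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0.3, seed = 8)
  pars <- random_params(g, 3, K = 2, seed = 9)
  s1 <- simulate_dataset(g, x, pars, n_years = 3, seed = 11)
  s2 <- simulate_dataset(g, x, pars, n_years = 3, seed = 11)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth$rr_surface, s2$truth$rr_surface)
  s3 <- simulate_dataset(g, x, pars, n_years = 3, seed = 12)
  expect_false(identical(s1$panel, s3$panel))
})

test_that("ground truth stores the exact RR functional of the parameters", {
  g <- make_lattice_graph(3, 3)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0.3, seed = 8)
  pars <- random_params(g, 3, K = 2, seed = 9)
  sim <- simulate_dataset(g, x, pars, n_years = 3, seed = 11)
  b <- spatial_effect(pars)
  rr_oracle <- exp(as.numeric(x %*% pars$beta_p) + b +
                     matrix(pars$gamma + pars$phi_t, 9, 3, byrow = TRUE) +
                     pars$psi)
  expect_equal(unname(sim$truth$rr_surface), rr_oracle, tolerance = 1e-12)
})

test_that("dimension mismatches are rejected", {
  g <- make_lattice_graph(3, 3)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0.3, seed = 1)
  pars <- random_params(g, 3, K = 2, seed = 2)
  expect_error(simulate_dataset(g, x, pars, n_years = 4, seed = 1), "mismatch")
  expect_error(simulate_dataset(g, x[1:5, ], pars, n_years = 3, seed = 1),
               "mismatch")
})
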