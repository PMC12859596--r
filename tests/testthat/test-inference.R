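test_that("sampling is a pure function of the seed", {
  g <- make_lattice_graph(3, 3)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0, seed = 1)
  pars <- random_params(g, 3, K = 2, seed = 2)
  sim <- simulate_dataset(g, x, pars, n_years = 3, seed = 3)
  args <- list(sim$truth$totals, sim$truth$E, x, g, hp_model_spec(),
               n_chains = 2, n_iter = 300, n_warmup = 150, seed = 77)
  f1 <- do.call(run_mcmc, args)
  f2 <- do.call(run_mcmc, args)
  expect_identical(f1$chains, f2$chains)
  args$seed <- 78
  f3 <- do.call(run_mcmc, args)
  expect_false(identical(f1$chains, f3$chains))
})

test_that("fixed-effects posterior matches the optimizer oracle", {
  # 500 cells, no random effects: the sampler and optim share one objective
  n <- 100L; T_ <- 5L; K <- 3L
  g <- make_lattice_graph(10, 10)
  x <- simulate_covariates(g, K = K, spatial_corr = 0, seed = 2)
  pars <- zero_params(n, T_, K, alpha_p = 0.2, alpha_b = 0.7,
                      beta_p = c(0.3, -0.2, 0), beta_b = c(0.2, 0, 0))
  sim <- simulate_dataset(g, x, pars, n_years = T_, seed = 11)
  y <- sim$truth$totals; E <- sim$truth$E
  spec <- hp_model_spec(include_spatial = FALSE, include_temporal = FALSE,
                        include_interaction = FALSE, share_scales_free = FALSE)
  obj <- function(th) {
    p <- zero_params(n, T_, K, alpha_p = th[1], alpha_b = th[2],
                     beta_p = th[3:(2 + K)], beta_b = th[(3 + K):(2 + 2 * K)])
    -log_posterior(p, spec, y, E, x, g)
  }
  opt <- optim(rep(0, 2 + 2 * K), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  fit <- run_mcmc(y, E, x, g, spec, n_chains = 4, n_iter = 5000,
                  n_warmup = 2500, seed = 3)
  fx <- stack_draws(fit, "fixed")
  d <- convergence_diagnostics(fit)
  expect_true(attr(d, "pass"))
  for (k in seq_len(K)) {
    col <- paste0("beta_p_cov", k)
    ess <- d$ess[d$param == col]
    mcse <- sd(fx[, col]) / sqrt(ess)
    expect_lt(abs(mean(fx[, col]) - opt$par[2 + k]), 3 * mcse)
  }
})

test_that("a prior-only run reproduces the PC-prior moments", {
  g <- make_lattice_graph(4, 4)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0, seed = 1)
  y <- matrix(0L, 16, 3); E <- matrix(1, 16, 3)
  fit <- run_mcmc(y, E, x, g, hp_model_spec(), n_chains = 2, n_iter = 11000,
                  n_warmup = 1000, thin = 5, seed = 5, prior_only = TRUE)
  h <- stack_draws(fit, "hyper")
  lam <- -log(0.01) / 1
  # quadrature oracles for the exponential PC prior on sigma
  m_sigma <- integrate(function(s) s * lam * exp(-lam * s), 0, Inf)$value
  m_logsig <- integrate(function(s) log(s) * lam * exp(-lam * s), 0, Inf)$value
  for (nm in c("sigma_b", "sigma_g", "sigma_f", "sigma_psi")) {
    draws <- h[, nm]
    ess <- hpmap:::ess_basic(cbind(draws[seq_len(2000)], draws[2001:4000]))
    expect_lt(abs(mean(draws) - m_sigma), 4 * sd(draws) / sqrt(ess))
    expect_lt(abs(mean(log(draws)) - m_logsig),
              4 * sd(log(draws)) / sqrt(ess))
  }
  # sharing coefficients: log-normal(0, 1) prior
  expect_lt(abs(mean(log(h[, "delta_s"]))), 4 * sd(log(h[, "delta_s"])) /
              sqrt(hpmap:::ess_basic(matrix(log(h[, "delta_s"]), ncol = 2))))
  # fixed effects: N(0, 10)
  fx <- stack_draws(fit, "fixed")
  expect_equal(sd(fx[, "alpha_p"]), 10, tolerance = 0.15)
})

test_that("split R-hat and ESS behave on designed chains", {
  S <- 1000L
  make <- function(ch1, ch2) {
    m <- length(ch1) + length(ch2)
    fake_samples(beta_p = matrix(c(ch1, ch2), ncol = 1),
                 b = matrix(c(ch1, ch2), ncol = 1),
                 gamma = matrix(c(ch1, ch2), ncol = 1),
                 phi_t = matrix(0, m, 1),
                 psi = matrix(0, m, 1))
  }
  set.seed(1)
  good <- make(rnorm(S), rnorm(S))
  dg <- convergence_diagnostics(good)
  r <- dg$rhat[dg$param == "beta_p_cov1"]
  expect_gt(r, 0.99); expect_lt(r, 1.01)
  expect_gt(dg$ess[dg$param == "beta_p_cov1"], 1000)

  bad <- make(rnorm(S), rnorm(S) + 10)
  db <- convergence_diagnostics(bad)
  expect_gt(db$rhat[db$param == "beta_p_cov1"], 1.2)
  expect_false(attr(db, "pass"))

  flat <- make(rep(1, S), rep(1, S))
  df <- convergence_diagnostics(flat)
  expect_true(df$degenerate[df$param == "beta_p_cov1"])
  expect_false(attr(df, "pass"))

  one_chain <- good
  one_chain$chains <- one_chain$chains[1]
  expect_error(convergence_diagnostics(one_chain), "2 chains")
  short <- make(rnorm(10), rnorm(10))
  expect_error(convergence_diagnostics(short), "100")
})

test_that("posterior ranks are uniform under simulation-based calibration", {
  # reduced SBC: fixed effects + BYM2 spatial on a 6x6 lattice
  g <- make_lattice_graph(6, 6); n <- g$n_areas; T_ <- 3L; K <- 1L
  x <- simulate_covariates(g, K = K, spatial_corr = 0, seed = 10)
  spec <- hp_model_spec(include_temporal = FALSE, include_interaction = FALSE,
                        share_scales_free = FALSE, fixed_prior_sd = 0.5)
  prec <- icar_precision(g)
  pphi <- pc_phi_prior(prec, g$component)
  lam <- -log(spec$pc_alpha) / spec$pc_u
  M <- 100L; L <- 100L
  ranks <- vapply(seq_len(M), function(r) {
    set.seed(1000 + r)
    sigma_b <- rexp(1, lam)
    pr <- exp(pphi$logprior); pr <- pr / sum(pr)
    phi <- sample(pphi$phi, 1, prob = pr)
    beta <- rnorm(K, 0, spec$fixed_prior_sd)
    pars <- zero_params(n, T_, K,
                        alpha_p = rnorm(1, 0, 0.5), alpha_b = rnorm(1, 0, 0.5),
                        beta_p = beta, beta_b = rnorm(K, 0, 0.5),
                        phi = phi, tau_b = 1 / sigma_b^2)
    pars$u <- hpmap:::sample_intrinsic(prec, g$component)
    pars$v <- rnorm(n)
    sim <- simulate_dataset(g, x, pars, n_years = T_, seed = 2000 + r)
    fit <- run_mcmc(sim$truth$totals, sim$truth$E, x, g, spec,
                    n_chains = 1, n_iter = 1000 + 10 * L, n_warmup = 1000,
                    thin = 10, seed = 3000 + r)
    sum(stack_draws(fit, "fixed")[, "beta_p_cov1"] < beta)
  }, 0)
  counts <- tabulate(findInterval(ranks, seq(0, L, length.out = 11),
                                  rightmost.closed = TRUE), nbins = 10L)
  # ranks take L + 1 values; the last bin holds one more than the others
  pval <- stats::chisq.test(counts, p = c(rep(10, 9), 11) / 101)$p.value
  expect_gt(pval, 0.01)
})
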