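test_that("ICAR precision is D - W with zero row sums and component rank", {
  path2 <- area_graph(2, rbind(c(1, 2)))
  p2 <- icar_precision(path2)
  expect_equal(as.matrix(p2$Q), rbind(c(1, -1), c(-1, 1)),
               ignore_attr = TRUE)
  for (g in list(make_lattice_graph(3, 3),
                 area_graph(6, rbind(c(1, 2), c(2, 3), c(4, 5))))) {
    p <- icar_precision(g)
    expect_lt(max(abs(Matrix::rowSums(p$Q))), 1e-12)
    expect_equal(p$rank_deficiency, max(g$component))
    # numeric rank check: zero eigenvalues = number of components
    ev <- eigen(as.matrix(p$Q), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-9), max(g$component))
  }
})

test_that("BYM2 scaling equals the dense constrained pseudo-inverse oracle", {
  for (g in list(make_lattice_graph(3, 3), make_lattice_graph(5, 5),
                 area_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4))))) {
    p <- icar_precision(g)
    mv <- dense_marginal_vars(as.matrix(p$Q))
    expect_lt(abs(p$scaling - exp(mean(log(mv)))), 1e-8)
  }
})

test_that("RW1 precision penalises first differences", {
  p2 <- rw1_precision(2)
  expect_equal(as.matrix(p2$Q), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  expect_equal(p2$rank_deficiency, 1L)
  p4 <- rw1_precision(4)
  for (i in 1:5) {
    x <- rnorm(4)
    expect_equal(as.numeric(t(x) %*% p4$Q %*% x), sum(diff(x)^2),
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(as.numeric(p4$Q %*% rep(1, 4)))), 1e-12)
  expect_error(rw1_precision(1), ">= 2")
})

test_that("intrinsic GMRF log-density matches a dense eigendecomposition", {
  for (obj in list(list(g = make_lattice_graph(4, 4)),
                   list(g = area_graph(7, rbind(c(1, 2), c(2, 3), c(4, 5),
                                                c(5, 6), c(6, 7)))))) {
    g <- obj$g
    p <- icar_precision(g)
    # draw a field obeying the constraints
    set.seed(99)
    x <- rnorm(g$n_areas)
    deg <- graph_degrees(g)
    x[deg == 0] <- 0
    for (cc in unique(g$component)) {
      nodes <- which(g$component == cc & deg > 0)
      if (length(nodes)) x[nodes] <- x[nodes] - mean(x[nodes])
    }
    tau <- 1.7
    keep <- which(deg > 0)
    Qs <- p$scaling * as.matrix(p$Q[keep, keep])
    ev <- eigen(Qs, symmetric = TRUE, only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-10
    oracle <- 0.5 * sum(pos) * log(tau) + 0.5 * sum(log(ev[pos])) -
      0.5 * sum(pos) * log(2 * pi) -
      0.5 * tau * as.numeric(t(x[keep]) %*% Qs %*% x[keep])
    expect_equal(gmrf_logdensity(x, p, tau), oracle, tolerance = 1e-9)
  }
})

test_that("linear predictors compose offset, covariates and shared effects", {
  n <- 4L; T_ <- 3L; K <- 2L
  x <- matrix(rnorm(n * K), n, K)
  E <- matrix(1, n, T_)
  pars <- zero_params(n, T_, K, alpha_p = 0.7, alpha_b = -0.4)
  lp <- linear_predictors(pars, x, E)
  expect_true(all(abs(lp$mu - exp(0.7)) < 1e-12))
  expect_true(all(abs(lp$pi - plogis(-0.4)) < 1e-12))

  # doubling E shifts eta_p by log 2 and leaves eta_b untouched
  lp2 <- linear_predictors(pars, x, 2 * E)
  expect_equal(lp2$eta_p, lp$eta_p + log(2), tolerance = 1e-12)
  expect_equal(lp2$eta_b, lp$eta_b, tolerance = 1e-15)

  # zero sharing coefficients strip the random effects from eta_b
  pars3 <- random_params(make_lattice_graph(2, 2), T_, K = K, seed = 1,
                         delta_s = 0, delta_t = 0, delta_st = 0)
  lp3 <- linear_predictors(pars3, x, E)
  expect_equal(lp3$eta_b,
               matrix(pars3$alpha_b + as.numeric(x %*% pars3$beta_b), n, T_),
               tolerance = 1e-12)
  expect_error(linear_predictors(pars, x, E * 0), "positive")
})

test_that("hurdle log-likelihood matches hand-computed and ZTP-pmf oracles", {
  expect_equal(hurdle_loglik(0, pi = 0.25, mu = 1), log(0.75), tolerance = 1e-12)
  # y = 1, pi = 0.5, mu = 1: log .5 + log(e^-1 / (1 - e^-1))
  oracle <- log(0.5) + dpois(1, 1, log = TRUE) - log(1 - dpois(0, 1))
  expect_equal(hurdle_loglik(1, 0.5, 1), oracle, tolerance = 1e-12)
  expect_equal(oracle, -1.234472, tolerance = 1e-6)
  # count-component pmf normalises over k >= 1 (mu = 3)
  ks <- 1:200
  lls <- vapply(ks, function(k) hurdle_loglik(k, 0.5, 3), 0) - log(0.5)
  expect_lt(abs(sum(exp(lls)) - 1), 1e-10)
  expect_error(hurdle_loglik(-1, 0.5, 1), "non-negative")
  expect_error(hurdle_loglik(1.5, 0.5, 1), "non-negative")
  expect_error(hurdle_loglik(1, 1, 1), "0, 1")
})

test_that("hurdle likelihood nests the Poisson when pi = 1 - e^-mu", {
  set.seed(123)
  y <- rpois(1000, 1.3)
  mu <- exp(rnorm(1000, 0, 0.5))
  pi <- 1 - exp(-mu)
  expect_lt(abs(hurdle_loglik(y, pi, mu) - sum(dpois(y, mu, log = TRUE))),
            1e-9)
})

test_that("log-posterior equals the sum of independently computed ordinates", {
  g <- make_lattice_graph(3, 3)
  n <- 9L; T_ <- 4L; K <- 2L
  x <- simulate_covariates(g, K = K, spatial_corr = 0, seed = 1)
  E <- matrix(1.2, n, T_)
  set.seed(5)
  y <- matrix(rpois(n * T_, 1), n, T_)
  spec <- hp_model_spec()
  tau0 <- pc_prec_median()
  pars <- zero_params(n, T_, K, tau = tau0, alpha_p = 0.3, alpha_b = -0.2,
                      beta_p = c(0.1, 0), beta_b = c(0, 0.2))
  got <- log_posterior(pars, spec, y, E, x, g)

  lp <- linear_predictors(pars, x, E)
  lam <- -log(spec$pc_alpha) / spec$pc_u
  p <- icar_precision(g)
  ev_s <- eigen(p$scaling * as.matrix(p$Q), symmetric = TRUE,
                only.values = TRUE)$values
  ev_s <- ev_s[ev_s > max(ev_s) * 1e-10]
  rw <- rw1_precision(T_)
  ev_t <- eigen(rw$scaling * as.matrix(rw$Q), symmetric = TRUE,
                only.values = TRUE)$values
  ev_t <- ev_t[ev_t > max(ev_t) * 1e-10]
  # PC prior for phi evaluated from first principles at phi = 0.5
  gam_cov <- 1 / ev_s
  kld <- function(ph) 0.5 * sum(ph * (c(gam_cov, 0) - 1) -
                                  log1p(ph * (c(gam_cov, 0) - 1)))
  dd <- function(ph) sqrt(2 * kld(ph))
  # oracle lambda by matching P(phi < 0.5) = 0.5 on a fine grid
  grid <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  dg <- vapply(grid, dd, 0)
  f_of <- function(l) {
    w <- exp(-l * dg) * c(diff(dg)[1], diff(dg))
    sum(w[grid < 0.5]) / sum(w) - 0.5
  }
  lam_phi <- uniroot(f_of, c(-50, 50), tol = 1e-9)$root
  dprime_mid <- (dd(0.5 + 1e-6) - dd(0.5 - 1e-6)) / 2e-6
  logphi_ord <- log(abs(lam_phi)) - lam_phi * dd(0.5) -
    log(abs(-expm1(-lam_phi * dd(1 - 1e-6)))) + log(dprime_mid)

  oracle <- hurdle_loglik(y, lp$pi, lp$mu) +
    sum(dnorm(c(0.3, -0.2, 0.1, 0, 0, 0.2), 0, 10, log = TRUE)) +
    # u = 0: scaled-ICAR ordinate at zero (rank-adjusted)
    (0.5 * sum(log(ev_s)) - 0.5 * length(ev_s) * log(2 * pi)) +
    sum(dnorm(rep(0, n), 0, 1, log = TRUE)) +                       # v
    (log(lam / 2) - 1.5 * log(tau0) - lam / sqrt(tau0)) +           # tau_b
    logphi_ord +
    # gamma = 0 at precision tau0 on the scaled RW1
    (0.5 * length(ev_t) * log(tau0) + 0.5 * sum(log(ev_t)) -
       0.5 * length(ev_t) * log(2 * pi)) +
    (log(lam / 2) - 1.5 * log(tau0) - lam / sqrt(tau0)) +           # tau_g
    sum(dnorm(rep(0, T_), 0, 1 / sqrt(tau0), log = TRUE)) +         # phi_t
    (log(lam / 2) - 1.5 * log(tau0) - lam / sqrt(tau0)) +           # tau_f
    sum(dnorm(rep(0, n * T_), 0, 1 / sqrt(tau0), log = TRUE)) +     # psi
    (log(lam / 2) - 1.5 * log(tau0) - lam / sqrt(tau0)) +           # tau_psi
    sum(dnorm(log(c(1, 1, 1)), 0, spec$share_prior_sd, log = TRUE) -
          log(c(1, 1, 1)))
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("log-posterior is invariant to recentred level shifts in gamma", {
  g <- make_lattice_graph(3, 3)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0, seed = 1)
  E <- matrix(1, 9, 4)
  set.seed(6)
  y <- matrix(rpois(36, 1), 9, 4)
  pars <- random_params(g, 4, K = 2, seed = 7)
  spec <- hp_model_spec()
  base <- log_posterior(pars, spec, y, E, x, g)
  shifted <- pars
  shifted$gamma <- (pars$gamma + 5) - mean(pars$gamma + 5)
  expect_equal(log_posterior(shifted, spec, y, E, x, g), base,
               tolerance = 1e-9)
})

test_that("raising mu towards an observed count raises the count likelihood", {
  y <- 5L
  mus <- seq(0.5, 5, by = 0.1)  # 1-d grid towards y
  lls <- vapply(mus, function(m) hurdle_loglik(y, 0.5, m), 0)
  expect_true(all(diff(lls) > 0))
})

test_that("log-posterior is exactly invariant under area relabelling", {
  g <- make_lattice_graph(3, 3)
  x <- simulate_covariates(g, K = 2, spatial_corr = 0.5, seed = 3)
  E <- matrix(1.5, 9, 3)
  set.seed(8)
  y <- matrix(rpois(27, 1), 9, 3)
  pars <- random_params(g, 3, K = 2, seed = 4)
  spec <- hp_model_spec()
  base <- log_posterior(pars, spec, y, E, x, g)
  perm <- sample(9)
  inv <- order(perm)
  g2 <- area_graph(9, cbind(inv[g$edges[, 1]], inv[g$edges[, 2]]))
  pars2 <- pars
  pars2$u <- pars$u[perm]; pars2$v <- pars$v[perm]
  pars2$psi <- pars$psi[perm, , drop = FALSE]
  expect_equal(log_posterior(pars2, spec, y[perm, ], E[perm, ], x[perm, ], g2),
               base, tolerance = 1e-9)
})
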