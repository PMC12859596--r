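zero_draws_samples <- function(S = 4L, n = 3L, T_ = 2L, K = 1L) {
  fake_samples(beta_p = matrix(0, S, K), b = matrix(0, S, n),
               gamma = matrix(0, S, T_), phi_t = matrix(0, S, T_),
               psi = matrix(0, S, n * T_))
}

test_that("null draws give RR = 1 with zero-width intervals", {
  s <- zero_draws_samples()
  x <- matrix(0, 3, 1)
  for (lv in c("area", "year", "area-year")) {
    rr <- relative_risk(s, x, lv)
    expect_true(all(rr$median == 1))
    expect_true(all(rr$ci_low == 1 & rr$ci_high == 1))
    expect_true(all(rr$exceedance == 0))  # RR exactly 1 never exceeds 1
  }
})

test_that("a constant spatial effect of log 2 doubles the area RR exactly", {
  s <- fake_samples(beta_p = matrix(0, 4, 1), b = matrix(log(2), 4, 1),
                    gamma = matrix(0, 4, 1), phi_t = matrix(0, 4, 1),
                    psi = matrix(0, 4, 1))
  rr <- relative_risk(s, matrix(0, 1, 1), "area")
  expect_equal(rr$median, 2, tolerance = 1e-12)
  expect_equal(rr$exceedance, 1)
})

test_that("hand-set draws match the enumeration oracle", {
  # 3 areas, 2 draws; covariate and spatial contributions hand-chosen
  bvals <- rbind(c(0.2, -0.1, 0), c(0.6, 0.1, -0.4))
  xm <- matrix(c(1, 0, -1), 3, 1)
  beta <- rbind(0.5, 0.1)
  s <- fake_samples(beta_p = beta, b = bvals,
                    gamma = matrix(0, 2, 1), phi_t = matrix(0, 2, 1),
                    psi = matrix(0, 2, 3))
  rr <- relative_risk(s, xm, "area")
  logdraws <- beta %*% t(xm) + bvals
  for (i in 1:3) {
    lo <- sort(logdraws[, i])
    # type-7 quantiles of two values: a + p (b - a), transformed back
    expect_equal(rr$median[i], exp(mean(lo)), tolerance = 1e-12)
    expect_equal(rr$ci_low[i], exp(lo[1] + 0.025 * diff(lo)), tolerance = 1e-12)
    expect_equal(rr$ci_high[i], exp(lo[1] + 0.975 * diff(lo)), tolerance = 1e-12)
    expect_equal(rr$exceedance[i], mean(logdraws[, i] > 0))
  }
})

test_that("RR contrasts are exact on constructed draws", {
  bvals <- rbind(c(log(2), 0), c(log(2), 0))
  s <- fake_samples(beta_p = matrix(0, 2, 1), b = bvals,
                    gamma = matrix(0, 2, 1), phi_t = matrix(0, 2, 1),
                    psi = matrix(0, 2, 2))
  x <- matrix(0, 2, 1)
  same <- rr_contrast(s, x, "area", "A0001", "A0001")
  expect_equal(same$median, 0)
  expect_equal(same$ci_low, 0)
  expect_equal(same$ci_high, 0)
  dbl <- rr_contrast(s, x, "area", "A0001", "A0002")
  expect_equal(dbl$median, 100, tolerance = 1e-12)
  # two differing draws: enumeration oracle on the log-ratio scale
  b2 <- rbind(c(0.3, 0), c(0.7, 0))
  s2 <- fake_samples(beta_p = matrix(0, 2, 1), b = b2,
                     gamma = matrix(0, 2, 1), phi_t = matrix(0, 2, 1),
                     psi = matrix(0, 2, 2))
  ct <- rr_contrast(s2, x, "area", "A0001", "A0002")
  lr <- sort(b2[, 1] - b2[, 2])
  expect_equal(ct$median, 100 * expm1(mean(lr)), tolerance = 1e-12)
  expect_equal(ct$ci_low, 100 * expm1(lr[1] + 0.025 * diff(lr)),
               tolerance = 1e-12)
  expect_error(rr_contrast(s2, x, "area", list(year = 1), "A0002"), "level")
})

test_that("exceedance bands are boundary-inclusive as published", {
  expect_equal(as.character(classify_exceedance(c(0, 0.2, 0.5, 0.8, 0.801, 1))),
               c("low", "low", "medium", "medium", "high", "high"))
  expect_error(classify_exceedance(-0.01), "0, 1")
  expect_error(classify_exceedance(1.01), "0, 1")
  # total monotone step function over a grid
  grid <- seq(0, 1, by = 0.001)
  lv <- as.integer(classify_exceedance(grid))
  expect_true(all(diff(lv) >= 0))
  expect_equal(sort(unique(lv)), 1:3)
})

test_that("percent change per SD follows the closed form and quantile rule", {
  expect_equal(percent_change_per_sd(rep(0, 10))$median, 0)
  expect_equal(percent_change_per_sd(rep(log(2), 10))$median, 100,
               tolerance = 1e-12)
  got <- percent_change_per_sd(c(0, log(1.5)))
  expect_equal(got$median, 100 * (sqrt(1.5) - 1), tolerance = 1e-12)
  expect_equal(got$median, 22.47449, tolerance = 1e-6)
  expect_equal(got$ci_low, 100 * (1.5^0.025 - 1), tolerance = 1e-12)
  expect_equal(got$ci_high, 100 * (1.5^0.975 - 1), tolerance = 1e-12)
  expect_error(percent_change_per_sd(numeric()), "non-empty")
})

test_that("variance decomposition attributes shares correctly", {
  # only covariate effects vary -> 100 / 0 / 0 / 0
  S <- 4L; n <- 10L; T_ <- 3L
  xm <- matrix(rnorm(n), n, 1)
  s <- fake_samples(beta_p = matrix(1, S, 1), b = matrix(0, S, n),
                    gamma = matrix(0, S, T_), phi_t = matrix(0, S, T_),
                    psi = matrix(0, S, n * T_))
  vd <- variance_decomposition(s, xm)
  expect_equal(vd$median[vd$component == "covariates"], 100, tolerance = 1e-9)
  expect_equal(vd$median[vd$component != "covariates"], rep(0, 3))

  # two independent equal-variance components with zero empirical covariance
  n2 <- 4L
  bv <- c(1, 1, -1, -1) / sqrt(2)
  xv <- c(1, -1, 1, -1) / sqrt(2)   # orthogonal to bv: zero covariance
  s2 <- fake_samples(beta_p = matrix(1, 2, 1), b = rbind(bv, bv),
                     gamma = matrix(0, 2, 1), phi_t = matrix(0, 2, 1),
                     psi = matrix(0, 2, n2))
  vd2 <- variance_decomposition(s2, matrix(xv, n2, 1))
  expect_equal(vd2$median[vd2$component == "covariates"], 50, tolerance = 1e-9)
  expect_equal(vd2$median[vd2$component == "spatial"], 50, tolerance = 1e-9)

  # negatively covarying components: shares sum above 100
  bv3 <- -0.9 * xv
  s3 <- fake_samples(beta_p = matrix(1, 2, 1), b = rbind(bv3, bv3),
                     gamma = matrix(0, 2, 1), phi_t = matrix(0, 2, 1),
                     psi = matrix(0, 2, n2))
  vd3 <- variance_decomposition(s3, matrix(xv, n2, 1))
  expect_gt(sum(vd3$median), 100)

  # all-zero draws are excluded; an all-degenerate set errors
  s4 <- zero_draws_samples()
  expect_error(suppressMessages(variance_decomposition(s4, matrix(0, 3, 1))),
               "half")
})

test_that("profile table bins partition units and track a matched covariate", {
  # covariate equal to log median RR must increase strictly across bins
  n <- 300L
  set.seed(21)
  z <- rnorm(n)
  rr <- data.frame(area_id = sprintf("A%04d", 1:n), year = 1L,
                   median = exp(z))
  prof <- profile_table(rr, matrix(z, n, 1, dimnames = list(NULL, "score")),
                        area_ids = sprintf("A%04d", 1:n))
  expect_equal(nrow(prof), 100L)
  expect_true(all(diff(prof$score) > 0))
  expect_equal(sum(prof$n_units), n)
  expect_true(all(abs(prof$n_units - 3) <= 1))

  # constant zero covariate -> all bin means zero
  prof0 <- profile_table(rr, matrix(0, n, 1), area_ids = sprintf("A%04d", 1:n))
  expect_true(all(prof0[, 3] == 0))

  # 200 units -> every bin has exactly 2
  rr2 <- rr[1:200, ]
  prof2 <- profile_table(rr2, matrix(z[1:200], 200, 1),
                         area_ids = sprintf("A%04d", 1:200))
  expect_true(all(prof2$n_units == 2L))

  # fewer units than bins reduces the bin count with a message
  expect_message(p3 <- profile_table(rr[1:50, ], matrix(z[1:50], 50, 1),
                                     area_ids = sprintf("A%04d", 1:50)),
                 "fewer units")
  expect_equal(nrow(p3), 50L)
})

test_that("exceedance, deficit and point mass at 1 partition the draws", {
  b <- rbind(c(0.5, 0, -0.3), c(-0.2, 0, 0.1), c(0.4, 0, 0.2), c(0.1, 0, -0.5))
  s <- fake_samples(beta_p = matrix(0, 4, 1), b = b,
                    gamma = matrix(0, 4, 1), phi_t = matrix(0, 4, 1),
                    psi = matrix(0, 4, 3))
  lr <- hpmap:::log_rr_draws(s, matrix(0, 3, 1), "area")
  p_above <- colMeans(lr$draws > 0)
  p_below <- colMeans(lr$draws < 0)
  p_at <- colMeans(lr$draws == 0)
  expect_equal(p_above + p_below + p_at, rep(1, 3))
})
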