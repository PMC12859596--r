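#' Hurdle-Poisson disease-mapping model specification
#'
#' Prior and structure choices for the two-component hurdle model. The count
#' component is a zero-truncated Poisson with log link and offset `log E`;
#' the occurrence component is a Bernoulli (logit link) on the indicator of
#' at least one event. Both components share a BYM2 spatial effect, a
#' RW1-plus-exchangeable temporal effect and an exchangeable (Type I)
#' space-time interaction; the occurrence component receives each shared
#' field multiplied by its own scalar sharing coefficient.
#'
#' Hyperpriors are penalised-complexity: `P(sigma > pc_u) = pc_alpha` for
#' each field standard deviation, and `P(phi < phi_u) = phi_alpha` for the
#' BYM2 mixing weight. Intercepts and covariate coefficients get
#' `N(0, fixed_prior_sd^2)` priors; the logs of the sharing coefficients get
#' `N(0, share_prior_sd^2)`.
#'
#' @param include_spatial,include_temporal,include_interaction Switch random
#'   effect blocks on/off (all on by default).
#' @param share_scales_free If `TRUE` (default) the sharing coefficients
#'   `delta_s`, `delta_t`, `delta_st` are estimated; if `FALSE` they are
#'   fixed at 1.
#' @param pc_u,pc_alpha PC-prior tail statement for every field standard
#'   deviation (defaults `u = 1`, `alpha = 0.01`).
#' @param phi_u,phi_alpha PC-prior tail statement for the BYM2 mixing weight
#'   (defaults `u = 0.5`, `alpha = 0.5`).
#' @param fixed_prior_sd Prior sd of intercepts and covariate coefficients.
#' @param share_prior_sd Prior sd of the log sharing coefficients.
#' @return An object of class `hp_model_spec`.
#' @export
hp_model_spec <- function(include_spatial = TRUE,
                          include_temporal = TRUE,
                          include_interaction = TRUE,
                          share_scales_free = TRUE,
                          pc_u = 1, pc_alpha = 0.01,
                          phi_u = 0.5, phi_alpha = 0.5,
                          fixed_prior_sd = 10,
                          share_prior_sd = 0.5) {
  if (pc_u <= 0 || pc_alpha <= 0 || pc_alpha >= 1) {
    stop("PC prior needs pc_u > 0 and pc_alpha in (0, 1)", call. = FALSE)
  }
  if (phi_u <= 0 || phi_u >= 1 || phi_alpha <= 0 || phi_alpha >= 1) {
    stop("PC prior needs phi_u and phi_alpha in (0, 1)", call. = FALSE)
  }
  if (fixed_prior_sd <= 0 || share_prior_sd <= 0) {
    stop("prior standard deviations must be positive", call. = FALSE)
  }
  structure(list(include_spatial = isTRUE(include_spatial),
                 include_temporal = isTRUE(include_temporal),
                 include_interaction = isTRUE(include_interaction),
                 share_scales_free = isTRUE(share_scales_free),
                 pc_u = pc_u, pc_alpha = pc_alpha,
                 phi_u = phi_u, phi_alpha = phi_alpha,
                 fixed_prior_sd = fixed_prior_sd,
                 share_prior_sd = share_prior_sd),
            class = "hp_model_spec")
}

#' @export
print.hp_model_spec <- function(x, ...) {
  cat("hp_model_spec:\n")
  cat("  random effects:",
      paste(c("spatial (BYM2)", "temporal (RW1 + iid)", "space-time (iid)")[
        c(x$include_spatial, x$include_temporal, x$include_interaction)],
        collapse = ", "), "\n")
  cat("  sharing coefficients:",
      if (x$share_scales_free) "estimated" else "fixed at 1", "\n")
  cat(sprintf("  PC priors: P(sigma > %g) = %g; P(phi < %g) = %g\n",
              x$pc_u, x$pc_alpha, x$phi_u, x$phi_alpha))
  invisible(x)
}

#' Latent parameter state of the hurdle model
#'
#' Collects the full latent state: intercepts and covariate coefficients for
#' the count (`_p`) and occurrence (`_b`) components, the BYM2 spatial pieces
#' (`u` scaled-structured, `v` unstructured, mixing `phi`, precision
#' `tau_b`), the temporal pieces (`gamma` RW1, precision `tau_g`; `phi_t`
#' exchangeable, precision `tau_f`), the space-time interaction (`psi`,
#' precision `tau_psi`), and the sharing coefficients `delta_s`, `delta_t`,
#' `delta_st`.
#'
#' `u` must sum to zero within each graph component (and be zero on isolated
#' areas); `gamma` must sum to zero overall.
#'
#' @param alpha_p,alpha_b Intercepts.
#' @param beta_p,beta_b Covariate coefficient vectors (length K).
#' @param u,v Structured / unstructured spatial fields (length `n_areas`).
#' @param phi BYM2 mixing weight in `[0, 1]`.
#' @param tau_b,tau_g,tau_f,tau_psi Field precisions (> 0).
#' @param gamma,phi_t Temporal fields (length `n_years`).
#' @param psi Interaction matrix (`n_areas x n_years`).
#' @param delta_s,delta_t,delta_st Sharing coefficients (> 0).
#' @param graph Optional [area_graph()] used to check the sum-to-zero
#'   constraint per connected component.
#' @return An object of class `hp_params`.
#' @export
hp_params <- function(alpha_p, alpha_b, beta_p, beta_b,
                      u, v, phi, tau_b,
                      gamma, tau_g, phi_t, tau_f,
                      psi, tau_psi,
                      delta_s = 1, delta_t = 1, delta_st = 1,
                      graph = NULL) {
  if (length(beta_p) != length(beta_b)) {
    stop("`beta_p` and `beta_b` must have equal length", call. = FALSE)
  }
  if (length(u) != length(v)) stop("`u` and `v` must have equal length", call. = FALSE)
  if (length(gamma) != length(phi_t)) {
    stop("`gamma` and `phi_t` must have equal length", call. = FALSE)
  }
  psi <- as.matrix(psi)
  if (nrow(psi) != length(u) || ncol(psi) != length(gamma)) {
    stop("`psi` must be n_areas x n_years", call. = FALSE)
  }
  taus <- c(tau_b = tau_b, tau_g = tau_g, tau_f = tau_f, tau_psi = tau_psi)
  if (any(taus <= 0)) stop("all precisions must be positive", call. = FALSE)
  if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(c(delta_s, delta_t, delta_st)))) {
    stop("sharing coefficients must be finite", call. = FALSE)
  }
  if (abs(sum(gamma)) > 1e-8 * max(1, sum(abs(gamma)))) {
    stop("`gamma` must sum to zero", call. = FALSE)
  }
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "area_graph"))
    deg <- graph_degrees(graph)
    for (cc in unique(graph$component)) {
      nodes <- which(graph$component == cc & deg > 0L)
      if (length(nodes) &&
          abs(sum(u[nodes])) > 1e-8 * max(1, sum(abs(u[nodes])))) {
        stop("`u` must sum to zero within each graph component", call. = FALSE)
      }
    }
    if (any(deg == 0L) && any(abs(u[deg == 0L]) > 1e-12)) {
      stop("`u` must be zero on isolated areas", call. = FALSE)
    }
  }
  structure(list(alpha_p = alpha_p, alpha_b = alpha_b,
                 beta_p = as.numeric(beta_p), beta_b = as.numeric(beta_b),
                 u = as.numeric(u), v = as.numeric(v),
                 phi = phi, tau_b = tau_b,
                 gamma = as.numeric(gamma), tau_g = tau_g,
                 phi_t = as.numeric(phi_t), tau_f = tau_f,
                 psi = psi, tau_psi = tau_psi,
                 delta_s = delta_s, delta_t = delta_t, delta_st = delta_st),
            class = "hp_params")
}

#' Composite BYM2 spatial effect
#'
#' `b = (1 / sqrt(tau_b)) * (sqrt(1 - phi) * v + sqrt(phi) * u)`.
#'
#' @param params An [hp_params()].
#' @return Numeric vector of length `n_areas`.
#' @export
spatial_effect <- function(params) {
  stopifnot(inherits(params, "hp_params"))
  (sqrt(1 - params$phi) * params$v + sqrt(params$phi) * params$u) /
    sqrt(params$tau_b)
}

#' All-zero parameter state
#'
#' Convenience constructor: every latent effect 0, precisions and sharing
#' coefficients at given values. Useful as a simulation baseline and as an
#' MCMC initial state.
#'
#' @param n_areas,n_years,K Dimensions.
#' @param tau Common value for all precisions.
#' @param ... Overrides passed on to [hp_params()].
#' @return An [hp_params()].
#' @export
zero_params <- function(n_areas, n_years, K, tau = 1, ...) {
  args <- list(alpha_p = 0, alpha_b = 0,
               beta_p = rep(0, K), beta_b = rep(0, K),
               u = rep(0, n_areas), v = rep(0, n_areas),
               phi = 0.5, tau_b = tau,
               gamma = rep(0, n_years), tau_g = tau,
               phi_t = rep(0, n_years), tau_f = tau,
               psi = matrix(0, n_areas, n_years), tau_psi = tau)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(hp_params, args)
}

#' Component linear predictors
#'
#' For area `i`, year `t`:
#' * count component: `eta_p = log E + alpha_p + x_i' beta_p + b_i + gamma_t
#'   + phi_t(t) + psi_it`, with `mu = exp(eta_p)`;
#' * occurrence component: `eta_b = alpha_b + x_i' beta_b + delta_s * b_i +
#'   delta_t * (gamma_t + phi_t(t)) + delta_st * psi_it`, with
#'   `pi = plogis(eta_b)`.
#'
#' The offset enters the count component only.
#'
#' @param params An [hp_params()].
#' @param covariates `n_areas x K` standardised covariate matrix.
#' @param E `n_areas x n_years` matrix of expected counts (strictly
#'   positive), or an `expected_counts` data frame.
#' @return List with matrices `eta_p`, `eta_b`, `mu`, `pi` (`n_areas x
#'   n_years`).
#' @export
linear_predictors <- function(params, covariates, E) {
  stopifnot(inherits(params, "hp_params"))
  covariates <- as.matrix(covariates)
  n <- length(params$u)
  T_ <- length(params$gamma)
  if (inherits(E, "expected_counts")) {
    E <- expected_matrix(E, sort(unique(E$area_id)), sort(unique(E$year)))
  }
  E <- as.matrix(E)
  if (nrow(covariates) != n || nrow(E) != n || ncol(E) != T_) {
    stop("dimension mismatch between params, covariates and E", call. = FALSE)
  }
  if (ncol(covariates) != length(params$beta_p)) {
    stop("covariate count does not match coefficient length", call. = FALSE)
  }
  if (any(E <= 0)) stop("expected counts must be strictly positive", call. = FALSE)
  b <- spatial_effect(params)
  xb_p <- as.numeric(covariates %*% params$beta_p)
  xb_b <- as.numeric(covariates %*% params$beta_b)
  tt <- params$gamma + params$phi_t
  eta_p <- log(E) + params$alpha_p + xb_p + b +
    matrix(tt, n, T_, byrow = TRUE) + params$psi
  eta_b <- params$alpha_b + xb_b + params$delta_s * b +
    matrix(params$delta_t * tt, n, T_, byrow = TRUE) +
    params$delta_st * params$psi
  list(eta_p = eta_p, eta_b = eta_b,
       mu = exp(eta_p), pi = stats::plogis(eta_b))
}

#' Hurdle log-likelihood
#'
#' Sum over cells of `log(1 - pi)` where `y = 0` and `log(pi) + y log(mu) -
#' mu - log(y!) - log(1 - e^-mu)` where `y >= 1` (Bernoulli gate times
#' zero-truncated Poisson).
#'
#' @param y Non-negative integer counts (vector or matrix).
#' @param pi Occurrence probabilities in (0, 1), same shape as `y`.
#' @param mu Positive ZTP rates, same shape as `y`.
#' @return Total log-likelihood (scalar).
#' @export
hurdle_loglik <- function(y, pi, mu) {
  y <- as.numeric(y); pi <- as.numeric(pi); mu <- as.numeric(mu)
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must contain non-negative integers", call. = FALSE)
  }
  if (any(pi <= 0) || any(pi >= 1)) stop("`pi` must lie in (0, 1)", call. = FALSE)
  pos <- y >= 1
  if (any(mu[pos] <= 0)) stop("`mu` must be positive where y >= 1", call. = FALSE)
  ll <- sum(log1p(-pi[!pos]))
  if (any(pos)) {
    ll <- ll + sum(log(pi[pos]) + y[pos] * log(mu[pos]) - mu[pos] -
                     lgamma(y[pos] + 1) - log(-expm1(-mu[pos])))
  }
  ll
}

# hurdle log-likelihood on the linear-predictor scale (no saturation at
# extreme eta_b; used by log_posterior so optimisers can roam freely)
hurdle_loglik_eta <- function(y, eta_b, eta_p) {
  y <- as.numeric(y); eta_b <- as.numeric(eta_b); eta_p <- as.numeric(eta_p)
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  pos <- y >= 1
  mu <- exp(eta_p[pos])
  sum(-softplus(eta_b[!pos])) +
    sum(eta_b[pos] - softplus(eta_b[pos]) + y[pos] * eta_p[pos] - mu -
          lgamma(y[pos] + 1) - log(-expm1(-mu)))
}

#' Joint log-posterior of the hurdle disease-mapping model
#'
#' Hurdle log-likelihood plus the latent Gaussian log-densities (BYM2
#' spatial, scaled RW1 and exchangeable temporal, exchangeable interaction),
#' the PC hyperprior ordinates for the precisions and mixing weight, and the
#' weakly-informative Gaussian priors on intercepts, coefficients and log
#' sharing coefficients. Intrinsic fields are evaluated on their constrained
#' subspace with rank-adjusted log-determinants.
#'
#' @param params An [hp_params()] satisfying its constraints.
#' @param spec An [hp_model_spec()].
#' @param y `n_areas x n_years` matrix of area-year totals.
#' @param E Matrix of expected counts (or `expected_counts` data frame).
#' @param covariates Standardised covariate matrix.
#' @param graph An [area_graph()].
#' @return The joint log-posterior (unnormalised), finite for valid params.
#' @export
log_posterior <- function(params, spec, y, E, covariates, graph) {
  stopifnot(inherits(params, "hp_params"), inherits(spec, "hp_model_spec"),
            inherits(graph, "area_graph"))
  lp <- linear_predictors(params, covariates, E)
  out <- hurdle_loglik_eta(y, lp$eta_b, lp$eta_p)
  sd0 <- spec$fixed_prior_sd
  out <- out + sum(stats::dnorm(c(params$alpha_p, params$alpha_b,
                                  params$beta_p, params$beta_b), 0, sd0, log = TRUE))
  if (spec$include_spatial) {
    prec <- icar_precision(graph)
    # non-centred BYM2: u is unit-scale scaled-ICAR, v unit white noise
    out <- out + gmrf_logdensity(params$u, prec, tau = 1)
    out <- out + sum(stats::dnorm(params$v, 0, 1, log = TRUE))
    out <- out + pc_prec_logprior(params$tau_b, spec$pc_u, spec$pc_alpha)
    pphi <- pc_phi_prior(prec, graph$component, spec$phi_u, spec$phi_alpha)
    out <- out + stats::approx(pphi$phi, pphi$logprior, xout = params$phi,
                               rule = 2)$y
  }
  if (spec$include_temporal) {
    rw <- rw1_precision(length(params$gamma))
    out <- out + gmrf_logdensity(params$gamma, rw, tau = params$tau_g)
    out <- out + pc_prec_logprior(params$tau_g, spec$pc_u, spec$pc_alpha)
    out <- out + sum(stats::dnorm(params$phi_t, 0, 1 / sqrt(params$tau_f), log = TRUE))
    out <- out + pc_prec_logprior(params$tau_f, spec$pc_u, spec$pc_alpha)
  }
  if (spec$include_interaction) {
    out <- out + sum(stats::dnorm(params$psi, 0, 1 / sqrt(params$tau_psi), log = TRUE))
    out <- out + pc_prec_logprior(params$tau_psi, spec$pc_u, spec$pc_alpha)
  }
  if (spec$share_scales_free) {
    deltas <- c(params$delta_s, params$delta_t, params$delta_st)
    if (any(deltas <= 0)) {
      stop("estimated sharing coefficients must be positive (log-normal prior)",
           call. = FALSE)
    }
    # log-normal prior: N(0, sd^2) on log delta, Jacobian 1/delta
    out <- out + sum(stats::dnorm(log(deltas), 0, spec$share_prior_sd, log = TRUE) -
                       log(deltas))
  }
  out
}
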