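#' Fit the hurdle disease-mapping model by MCMC
#'
#' Blocked adaptive Metropolis-within-Gibbs sampling of the joint posterior:
#' block random-walk updates for the intercept-plus-coefficient vector of
#' each component (acceptance tuned towards 0.23), single-site random-walk
#' updates for every latent field value (tuned towards 0.44), and log-scale
#' random-walk updates for standard deviations, the BYM2 mixing weight and
#' the sharing coefficients. Step sizes adapt in batches of 50 during warmup
#' and are frozen afterwards. Sum-to-zero constraints on the structured
#' spatial (per graph component) and temporal fields are enforced by
#' recentring within each sweep.
#'
#' Chains are initialised at crude moment-matching values with overdispersed
#' jitter, and each chain's random stream is seeded as `seed + chain - 1`,
#' so the full result is a pure function of the inputs.
#'
#' @param y `n_areas x n_years` matrix of area-year event totals.
#' @param E Matrix of positive expected counts (offset), or an
#'   `expected_counts` data frame.
#' @param covariates Standardised `n_areas x K` covariate matrix.
#' @param graph An [area_graph()].
#' @param spec An [hp_model_spec()].
#' @param n_chains,n_iter,n_warmup,thin MCMC settings (defaults 4 chains of
#'   5000 iterations, 2500 warmup, no thinning).
#' @param seed Integer seed.
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   sampler explores the prior (useful for prior-predictive checks).
#' @return An object of class `hp_samples`: list with `chains` (per chain,
#'   matrices `fixed`, `b`, `gamma`, `phi_t`, `psi`, `hyper`, vector
#'   `loglik`), `dims`, `spec` and `meta`.
#' @export
run_mcmc <- function(y, E, covariates, graph, spec = hp_model_spec(),
                     n_chains = 4L, n_iter = 5000L, n_warmup = 2500L,
                     thin = 1L, seed = 1L, prior_only = FALSE) {
  stopifnot(inherits(graph, "area_graph"), inherits(spec, "hp_model_spec"))
  y <- as.matrix(y)
  if (inherits(E, "expected_counts")) {
    E <- expected_matrix(E, sort(unique(E$area_id)), sort(unique(E$year)))
  }
  E <- as.matrix(E)
  covariates <- as.matrix(covariates)
  n <- graph$n_areas
  T_ <- ncol(y)
  K <- ncol(covariates)
  if (nrow(y) != n || nrow(E) != n || ncol(E) != T_ || nrow(covariates) != n) {
    stop("dimension mismatch between y, E, covariates and graph", call. = FALSE)
  }
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("expected counts must be finite and strictly positive", call. = FALSE)
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must contain non-negative integers", call. = FALSE)
  }
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_warmup <- as.integer(n_warmup); thin <- as.integer(thin)
  if (n_chains < 1L) stop("`n_chains` must be at least 1", call. = FALSE)
  if (n_warmup < 0L || n_iter <= n_warmup) {
    stop("need n_iter > n_warmup >= 0", call. = FALSE)
  }
  spec_run <- spec
  if (T_ < 2L && spec_run$include_temporal) {
    spec_run$include_temporal <- FALSE
    warning("single-year data: temporal effects disabled")
  }

  prec <- icar_precision(graph)
  if (spec_run$include_spatial) {
    pphi <- pc_phi_prior(prec, graph$component, spec_run$phi_u, spec_run$phi_alpha)
  } else {
    pphi <- list(phi = c(0, 1), logprior = c(0, 0))
  }
  rw_scale <- if (spec_run$include_temporal) rw1_precision(T_)$scaling else 1
  lambda_sig <- -log(spec_run$pc_alpha) / spec_run$pc_u
  nb0 <- lapply(graph_neighbours(graph), function(x) as.integer(x - 1L))

  ap0 <- if (sum(y) > 0) log(sum(y) / sum(E)) else -2
  ab0 <- stats::qlogis(min(max(mean(y > 0), 0.02), 0.98))

  chains <- vector("list", n_chains)
  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    init <- list(alpha_p = ap0 + stats::rnorm(1, 0, 0.3),
                 alpha_b = ab0 + stats::rnorm(1, 0, 0.3),
                 beta_p = stats::rnorm(K, 0, 0.1),
                 beta_b = stats::rnorm(K, 0, 0.1),
                 log_sigma_b = log(0.5) + stats::rnorm(1, 0, 0.3),
                 phi = 0.5,
                 log_sigma_g = log(0.3) + stats::rnorm(1, 0, 0.3),
                 log_sigma_f = log(0.3) + stats::rnorm(1, 0, 0.3),
                 log_sigma_psi = log(0.3) + stats::rnorm(1, 0, 0.3),
                 log_delta_s = 0, log_delta_t = 0, log_delta_st = 0)
    raw <- hp_mcmc_chain(
      y = matrix(as.integer(y), n, T_), logE = log(E), X = covariates,
      nb = nb0, comp = graph$component,
      icar_scale = prec$scaling, rw_scale = rw_scale,
      incl_sp = spec_run$include_spatial,
      incl_tm = spec_run$include_temporal,
      incl_int = spec_run$include_interaction,
      share_free = spec_run$share_scales_free,
      prior_only = isTRUE(prior_only),
      lambda_sig = lambda_sig,
      phi_grid = pphi$phi, phi_logp = pphi$logprior,
      sd_fixed = spec_run$fixed_prior_sd, sd_share = spec_run$share_prior_sd,
      n_iter = n_iter, n_warmup = n_warmup, thin = thin,
      init = init)
    cn <- colnames(covariates)
    if (is.null(cn)) cn <- paste0("cov", seq_len(K))
    colnames(raw$fixed) <- c("alpha_p", "alpha_b",
                             paste0("beta_p_", cn), paste0("beta_b_", cn))
    colnames(raw$hyper) <- c("sigma_b", "phi", "sigma_g", "sigma_f",
                             "sigma_psi", "delta_s", "delta_t", "delta_st")
    chains[[ch]] <- raw
  }
  area_ids <- rownames(y)
  if (is.null(area_ids)) area_ids <- sprintf("A%04d", seq_len(n))
  years <- suppressWarnings(as.integer(colnames(y)))
  if (is.null(colnames(y)) || anyNA(years)) years <- seq_len(T_)
  structure(list(
    chains = chains,
    dims = list(n_areas = n, n_years = T_, K = K,
                area_ids = area_ids, years = years,
                covariate_names = if (is.null(colnames(covariates)))
                  paste0("cov", seq_len(K)) else colnames(covariates)),
    spec = spec_run,
    meta = list(seed = as.integer(seed), n_chains = n_chains,
                n_iter = n_iter, n_warmup = n_warmup, thin = thin,
                prior_only = isTRUE(prior_only),
                runtime_s = proc.time()[["elapsed"]] - t0)),
    class = "hp_samples")
}

#' @export
print.hp_samples <- function(x, ...) {
  s <- nrow(x$chains[[1L]]$fixed)
  cat(sprintf("hp_samples: %d chain(s) x %d stored draws; %d areas x %d years, K = %d\n",
              length(x$chains), s, x$dims$n_areas, x$dims$n_years, x$dims$K))
  invisible(x)
}

#' Stack posterior draws across chains
#'
#' @param samples An `hp_samples` object.
#' @param field One of `"fixed"`, `"b"`, `"gamma"`, `"phi_t"`, `"psi"`,
#'   `"hyper"`, `"loglik"`.
#' @return Matrix (or vector for `loglik`) with all chains' post-warmup
#'   draws stacked row-wise.
#' @export
stack_draws <- function(samples, field) {
  stopifnot(inherits(samples, "hp_samples"))
  parts <- lapply(samples$chains, `[[`, field)
  if (is.null(parts[[1L]])) stop("unknown field: ", field, call. = FALSE)
  if (is.matrix(parts[[1L]])) do.call(rbind, parts) else do.call(c, parts)
}

split_rhat <- function(draws) {
  # draws: iterations x chains; split each chain in half
  N <- nrow(draws)
  if (N < 4L) return(NA_real_)
  half <- N %/% 2L
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(N - half + 1L):N, , drop = FALSE])
  m <- colMeans(sub)
  v <- apply(sub, 2L, stats::var)
  W <- mean(v)
  B <- half * stats::var(m)
  if (!is.finite(W) || W == 0) return(NA_real_)
  var_hat <- (half - 1) / half * W + B / half
  sqrt(var_hat / W)
}

ess_basic <- function(draws) {
  # combined-chain effective sample size via Geyer initial positive sequence
  N <- nrow(draws); M <- ncol(draws)
  if (N < 4L) return(NA_real_)
  v <- apply(draws, 2L, stats::var)
  W <- mean(v)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- N * stats::var(colMeans(draws))
  var_hat <- (N - 1) / N * W + B / N
  max_lag <- min(N - 2L, 200L)
  acov <- sapply(seq_len(M), function(ch) {
    stats::acf(draws[, ch], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  })
  rho <- 1 - (W - rowMeans(acov)[-1L]) / var_hat
  # pair lags (1,2), (3,4), ... and stop at the first non-positive pair sum
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    p <- rho[t] + rho[t + 1L]
    if (!is.finite(p) || p <= 0) break
    s <- s + p
    t <- t + 2L
  }
  max(N * M / (1 + 2 * s), 1)
}

#' Convergence diagnostics for posterior samples
#'
#' Computes split-R-hat and effective sample size for every fixed-effect and
#' hyperparameter column and a leading subset of the latent fields. The
#' overall `pass` attribute is `TRUE` when every monitored, non-degenerate
#' quantity has split-R-hat below 1.05 and nothing is degenerate.
#'
#' @param samples An `hp_samples` object with at least 2 chains and 100
#'   stored draws per chain.
#' @param rhat_limit Pass threshold (default 1.05).
#' @return Data frame with columns `param`, `mean`, `sd`, `rhat`, `ess`,
#'   `degenerate`; attribute `pass` (logical).
#' @export
convergence_diagnostics <- function(samples, rhat_limit = 1.05) {
  stopifnot(inherits(samples, "hp_samples"))
  M <- length(samples$chains)
  if (M < 2L) stop("diagnostics require at least 2 chains", call. = FALSE)
  N <- nrow(samples$chains[[1L]]$fixed)
  if (is.null(N) || N < 100L) {
    stop("diagnostics require at least 100 stored draws per chain", call. = FALSE)
  }
  take <- function(field, max_cols = Inf) {
    m <- samples$chains[[1L]][[field]]
    if (is.null(m) || !is.matrix(m) || ncol(m) == 0L) return(NULL)
    cols <- seq_len(min(ncol(m), max_cols))
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0(field, "[", seq_len(ncol(m)), "]")
    lapply(cols, function(j) {
      d <- sapply(samples$chains, function(ch) ch[[field]][, j])
      list(name = cn[j], draws = d)
    })
  }
  spec <- samples$spec
  sp_on <- is.null(spec) || spec$include_spatial
  tm_on <- is.null(spec) || spec$include_temporal
  monitored <- c(take("fixed"), take("hyper"),
                 if (sp_on) take("b", 5L),
                 if (tm_on) c(take("gamma", 5L), take("phi_t", 5L)))
  # hyperparameters of switched-off components are fixed by design, not stuck
  if (!is.null(spec)) {
    off <- character()
    if (!spec$include_spatial) off <- c(off, "sigma_b", "phi")
    if (!spec$include_temporal) off <- c(off, "sigma_g", "sigma_f", "delta_t")
    if (!spec$include_interaction) off <- c(off, "sigma_psi", "delta_st")
    if (!spec$share_scales_free) off <- c(off, "delta_s", "delta_t", "delta_st")
    if (!spec$include_spatial) off <- c(off, "delta_s")
    monitored <- Filter(function(p) !(p$name %in% off), monitored)
  }
  rows <- lapply(monitored, function(p) {
    d <- p$draws
    sd_all <- stats::sd(as.numeric(d))
    degenerate <- !is.finite(sd_all) || sd_all == 0
    data.frame(param = p$name,
               mean = mean(d), sd = sd_all,
               rhat = if (degenerate) NA_real_ else split_rhat(d),
               ess = if (degenerate) NA_real_ else ess_basic(d),
               degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !out$degenerate & is.finite(out$rhat)
  pass <- !any(out$degenerate) && all(out$rhat[ok] < rhat_limit) && any(ok)
  attr(out, "pass") <- pass
  class(out) <- c("hp_diagnostics", "data.frame")
  out
}

#' @export
print.hp_diagnostics <- function(x, ...) {
  cat(sprintf("convergence diagnostics: %d monitored quantities, pass = %s\n",
              nrow(x), attr(x, "pass")))
  worst <- x[order(-ifelse(is.finite(x$rhat), x$rhat, Inf)), ]
  print.data.frame(utils::head(worst, 10L), row.names = FALSE, digits = 3)
  invisible(x)
}
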