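#' Posterior relative-risk summaries
#'
#' Relative risks are functionals of the latent state, per posterior draw:
#' * `year`: `RR_t = exp(gamma_t + phi_t)` — risk of each year relative to
#'   the study-period average (the temporal fields sum to zero);
#' * `area`: `RR_i = exp(x_i' beta_p + b_i)` — risk of each area relative to
#'   the average area with the same age-sex structure (covariates are
#'   standardised, so their contribution is centred);
#' * `area-year`: `RR_it = exp(x_i' beta_p + b_i + gamma_t + phi_t + psi_it)`;
#' * `region-year`: expected-count-weighted mean of the area-year RR draws
#'   over the areas of each region.
#'
#' Summaries are the posterior median and equal-tailed credible interval
#' (quantiles computed on the log scale with the standard linear
#' interpolation rule, then exponentiated — monotone-equivariant), plus the
#' exceedance probability `P(RR > 1)` (strict inequality).
#'
#' @param samples An `hp_samples` object.
#' @param covariates Standardised covariate matrix used in the fit.
#' @param level One of `"area"`, `"year"`, `"area-year"`, `"region-year"`.
#' @param region_map For `region-year`: vector of region labels, one per
#'   area (in the order of `samples$dims$area_ids`), or a named vector
#'   keyed by area id.
#' @param weights For `region-year`: `n_areas x n_years` matrix of expected
#'   counts (or an `expected_counts` data frame) used as aggregation weights.
#' @param cri Credible level (default 0.95).
#' @return Data frame with unit columns (`area_id` and/or `year`, or
#'   `region`), `median`, `ci_low`, `ci_high`, `exceedance`; class
#'   `rr_summary` with attribute `level`.
#' @export
relative_risk <- function(samples, covariates,
                          level = c("area", "year", "area-year", "region-year"),
                          region_map = NULL, weights = NULL, cri = 0.95) {
  stopifnot(inherits(samples, "hp_samples"))
  level <- match.arg(level)
  d <- samples$dims
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != d$n_areas) stop("covariate rows must match areas", call. = FALSE)
  log_rr <- log_rr_draws(samples, covariates, level, region_map, weights)
  summarise_rr(log_rr$draws, log_rr$units, cri)
}

# per-draw log-RR matrices with unit labels
log_rr_draws <- function(samples, covariates, level, region_map = NULL,
                         weights = NULL) {
  d <- samples$dims
  n <- d$n_areas; T_ <- d$n_years
  fixed <- stack_draws(samples, "fixed")
  bp <- fixed[, paste0("beta_p_", d$covariate_names), drop = FALSE]
  xb <- bp %*% t(covariates)                    # S x n
  if (level == "year") {
    tt <- stack_draws(samples, "gamma") + stack_draws(samples, "phi_t")
    return(list(draws = tt, units = data.frame(year = d$years)))
  }
  b <- stack_draws(samples, "b")
  if (level == "area") {
    return(list(draws = xb + b, units = data.frame(area_id = d$area_ids,
                                                   stringsAsFactors = FALSE)))
  }
  tt <- stack_draws(samples, "gamma") + stack_draws(samples, "phi_t")
  psi <- stack_draws(samples, "psi")            # S x (n*T), cell (t-1)*n + i
  ay <- xb[, rep(seq_len(n), T_), drop = FALSE] +
    b[, rep(seq_len(n), T_), drop = FALSE] +
    tt[, rep(seq_len(T_), each = n), drop = FALSE] + psi
  units <- data.frame(area_id = rep(d$area_ids, T_),
                      year = rep(d$years, each = n),
                      stringsAsFactors = FALSE)
  if (level == "area-year") return(list(draws = ay, units = units))
  # region-year
  if (is.null(region_map) || is.null(weights)) {
    stop("region-year summaries require `region_map` and `weights`", call. = FALSE)
  }
  if (!is.null(names(region_map))) {
    region_map <- region_map[d$area_ids]
    if (anyNA(region_map)) stop("`region_map` does not cover all areas", call. = FALSE)
  }
  if (length(region_map) != n) stop("`region_map` must have one entry per area", call. = FALSE)
  if (inherits(weights, "expected_counts")) {
    weights <- expected_matrix(weights, d$area_ids, d$years)
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != n || ncol(weights) != T_) {
    stop("`weights` must be n_areas x n_years", call. = FALSE)
  }
  rr <- exp(ay)
  regions <- sort(unique(as.character(region_map)))
  cols <- vector("list", length(regions) * T_)
  units_ry <- data.frame(region = character(), year = integer(),
                         stringsAsFactors = FALSE)
  k <- 0L
  out <- matrix(NA_real_, nrow(rr), length(regions) * T_)
  for (t_ in seq_len(T_)) {
    for (rg in regions) {
      k <- k + 1L
      sel <- which(region_map == rg)
      cell <- (t_ - 1L) * n + sel
      w <- weights[sel, t_]
      out[, k] <- as.numeric(rr[, cell, drop = FALSE] %*% (w / sum(w)))
      units_ry <- rbind(units_ry,
                        data.frame(region = rg, year = d$years[t_],
                                   stringsAsFactors = FALSE))
    }
  }
  list(draws = log(out), units = units_ry)
}

summarise_rr <- function(log_draws, units, cri = 0.95) {
  a <- (1 - cri) / 2
  qs <- apply(log_draws, 2L, stats::quantile, probs = c(0.5, a, 1 - a),
              names = FALSE, type = 7)
  out <- cbind(units,
               data.frame(median = exp(qs[1L, ]),
                          ci_low = exp(qs[2L, ]),
                          ci_high = exp(qs[3L, ]),
                          exceedance = colMeans(log_draws > 0)))
  rownames(out) <- NULL
  structure(out, class = c("rr_summary", "data.frame"))
}

#' Percent contrast between two relative risks
#'
#' Per draw, `100 * (RR_a / RR_b - 1)`; summarised by the posterior median
#' and equal-tailed credible interval (computed on the log-ratio scale, then
#' transformed).
#'
#' @inheritParams relative_risk
#' @param unit_a,unit_b Unit identifiers at the chosen level: an area id,
#'   a year, a `list(area_id=, year=)`, or a `list(region=, year=)`.
#' @return One-row data frame with `median`, `ci_low`, `ci_high`
#'   (percentages).
#' @export
rr_contrast <- function(samples, covariates, level, unit_a, unit_b,
                        region_map = NULL, weights = NULL, cri = 0.95) {
  lr <- log_rr_draws(samples, as.matrix(covariates), level, region_map, weights)
  find <- function(u) {
    if (!is.list(u)) u <- as.list(stats::setNames(u, names(lr$units)[1L]))
    miss <- setdiff(names(u), names(lr$units))
    if (length(miss)) {
      stop("unit key(s) ", paste(miss, collapse = ", "),
           " do not match level '", level, "'", call. = FALSE)
    }
    sel <- rep(TRUE, nrow(lr$units))
    for (nm in names(u)) sel <- sel & lr$units[[nm]] == u[[nm]]
    idx <- which(sel)
    if (length(idx) != 1L) {
      stop("unit ", paste(unlist(u), collapse = "/"),
           " does not identify exactly one ", level, " unit", call. = FALSE)
    }
    idx
  }
  dlr <- lr$draws[, find(unit_a)] - lr$draws[, find(unit_b)]
  a <- (1 - cri) / 2
  q <- stats::quantile(dlr, probs = c(0.5, a, 1 - a), names = FALSE, type = 7)
  data.frame(median = 100 * expm1(q[1L]),
             ci_low = 100 * expm1(q[2L]),
             ci_high = 100 * expm1(q[3L]))
}

#' Band an exceedance probability into evidence categories
#'
#' `low` for `P(RR > 1)` in `[0, 0.2]`, `medium` for `(0.2, 0.8]`, `high`
#' for `(0.8, 1]` — boundary-inclusive on the right.
#'
#' @param p Exceedance probabilities in `[0, 1]` (vectorised).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_exceedance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  factor(ifelse(p <= 0.2, "low", ifelse(p <= 0.8, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Percent change in risk per standard-deviation increment
#'
#' Covariates enter the model standardised, so a coefficient `beta` is
#' already a per-SD log-risk change; the reported effect is
#' `100 * (exp(beta) - 1)`. Quantiles are computed on the coefficient scale
#' (standard linear-interpolation rule) and transformed.
#'
#' @param beta_draws Vector of posterior coefficient draws.
#' @param cri Credible level (default 0.95).
#' @return One-row data frame with `median`, `ci_low`, `ci_high`
#'   (percentages).
#' @export
percent_change_per_sd <- function(beta_draws, cri = 0.95) {
  beta_draws <- as.numeric(beta_draws)
  if (!length(beta_draws)) stop("`beta_draws` must be non-empty", call. = FALSE)
  a <- (1 - cri) / 2
  q <- stats::quantile(beta_draws, probs = c(0.5, a, 1 - a), names = FALSE,
                       type = 7)
  data.frame(median = 100 * expm1(q[1L]),
             ci_low = 100 * expm1(q[2L]),
             ci_high = 100 * expm1(q[3L]))
}

#' Covariate effect table
#'
#' Applies [percent_change_per_sd()] to each covariate coefficient of the
#' chosen component.
#'
#' @param samples An `hp_samples` object.
#' @param component `"count"` (Poisson, default) or `"occurrence"`
#'   (binomial gate).
#' @param cri Credible level.
#' @return Data frame with one row per covariate: `covariate`, `median`,
#'   `ci_low`, `ci_high`.
#' @export
covariate_effects <- function(samples, component = c("count", "occurrence"),
                              cri = 0.95) {
  stopifnot(inherits(samples, "hp_samples"))
  component <- match.arg(component)
  pre <- if (component == "count") "beta_p_" else "beta_b_"
  fixed <- stack_draws(samples, "fixed")
  cn <- samples$dims$covariate_names
  rows <- lapply(cn, function(nm) {
    cbind(data.frame(covariate = nm, stringsAsFactors = FALSE),
          percent_change_per_sd(fixed[, paste0(pre, nm)], cri))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

row_var <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Variance decomposition of the relative-risk surface
#'
#' Per draw, the empirical variances over all (area, year) units of the
#' covariate contribution `x_i' beta_p`, the spatial effect `b_i`, the
#' temporal effect `gamma_t + phi_t`, and the interaction `psi_it` are
#' expressed as percentages of the variance of their sum (the non-offset,
#' non-intercept count-component linear predictor). Because the components
#' can covary, the shares need not sum to 100.
#'
#' @param samples An `hp_samples` object.
#' @param covariates Standardised covariate matrix used in the fit.
#' @param cri Credible level (default 0.95).
#' @return Data frame with one row per component (`covariates`, `spatial`,
#'   `temporal`, `spatio-temporal`): `median`, `ci_low`, `ci_high`
#'   (percent shares); attribute `n_excluded` counts zero-variance draws.
#' @export
variance_decomposition <- function(samples, covariates, cri = 0.95) {
  stopifnot(inherits(samples, "hp_samples"))
  d <- samples$dims
  n <- d$n_areas; T_ <- d$n_years
  covariates <- as.matrix(covariates)
  fixed <- stack_draws(samples, "fixed")
  bp <- fixed[, paste0("beta_p_", d$covariate_names), drop = FALSE]
  xb <- bp %*% t(covariates)
  b <- stack_draws(samples, "b")
  tt <- stack_draws(samples, "gamma") + stack_draws(samples, "phi_t")
  psi <- stack_draws(samples, "psi")
  S <- nrow(xb)
  shares <- matrix(NA_real_, S, 4L,
                   dimnames = list(NULL, c("covariates", "spatial",
                                           "temporal", "spatio-temporal")))
  ia <- rep(seq_len(n), T_)
  it <- rep(seq_len(T_), each = n)
  block <- 256L
  for (s0 in seq(1L, S, by = block)) {
    s1 <- min(s0 + block - 1L, S)
    idx <- s0:s1
    cfull <- xb[idx, ia, drop = FALSE]
    bfull <- b[idx, ia, drop = FALSE]
    tfull <- tt[idx, it, drop = FALSE]
    pfull <- psi[idx, , drop = FALSE]
    vtot <- row_var(cfull + bfull + tfull + pfull)
    shares[idx, 1L] <- 100 * row_var(cfull) / vtot
    shares[idx, 2L] <- 100 * row_var(bfull) / vtot
    shares[idx, 3L] <- 100 * row_var(tfull) / vtot
    shares[idx, 4L] <- 100 * row_var(pfull) / vtot
  }
  ok <- is.finite(shares[, 1L])
  n_excluded <- sum(!ok)
  if (n_excluded > S / 2) {
    stop("variance decomposition undefined for more than half of the draws",
         call. = FALSE)
  }
  if (n_excluded > 0) {
    message(n_excluded, " draw(s) with zero total variance excluded")
  }
  a <- (1 - cri) / 2
  rows <- lapply(colnames(shares), function(cmp) {
    q <- stats::quantile(shares[ok, cmp], probs = c(0.5, a, 1 - a),
                         names = FALSE, type = 7)
    data.frame(component = cmp, median = q[1L], ci_low = q[2L], ci_high = q[3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Covariate profiles along the relative-risk ranking
#'
#' Ranks all (area, year) units by their posterior-median RR (ascending,
#' ties broken by stable unit order), partitions them into `n_bins`
#' near-equal bins (sizes differ by at most 1), and reports the mean of
#' each standardised covariate within every bin. Highlights which
#' combinations of area characteristics accompany the lowest and highest
#' risks.
#'
#' @param rr An area-year [relative_risk()] summary (columns `area_id`,
#'   `year`, `median`).
#' @param covariates Standardised covariate matrix with rows in sorted
#'   area-id order (area-level values are broadcast across years).
#' @param area_ids Area ids labelling the covariate rows (default: sorted
#'   unique `rr$area_id`).
#' @param n_bins Number of percentile bins (default 100; reduced with a
#'   message when there are fewer units).
#' @return Data frame: `percentile`, `n_units`, one mean-score column per
#'   covariate.
#' @export
profile_table <- function(rr, covariates, area_ids = NULL, n_bins = 100L) {
  if (!all(c("area_id", "year", "median") %in% names(rr))) {
    stop("`rr` must be an area-year RR summary", call. = FALSE)
  }
  covariates <- as.matrix(covariates)
  if (is.null(area_ids)) area_ids <- sort(unique(rr$area_id))
  if (nrow(covariates) != length(area_ids)) {
    stop("covariate rows must match `area_ids`", call. = FALSE)
  }
  idx <- match(rr$area_id, area_ids)
  if (anyNA(idx)) stop("`rr` contains area ids absent from `area_ids`", call. = FALSE)
  n_units <- nrow(rr)
  nb <- min(as.integer(n_bins), n_units)
  if (nb < n_bins) message("fewer units than bins: using ", nb, " bins")
  ord <- order(rr$median)  # stable: ties keep unit order
  base <- n_units %/% nb
  rem <- n_units %% nb
  sizes <- base + (seq_len(nb) <= rem)
  bin <- rep(seq_len(nb), times = sizes)
  out <- data.frame(percentile = seq_len(nb), n_units = sizes)
  for (j in seq_len(ncol(covariates))) {
    vals <- covariates[idx[ord], j]
    out[[colnames(covariates)[j] %||% paste0("cov", j)]] <-
      as.numeric(tapply(vals, bin, mean))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
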