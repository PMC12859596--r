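#' Default stratum baseline rates
#'
#' Plausible rare-event mortality rates (deaths per person-year) for 8
#' ten-year age bands by 2 sexes, with male rates roughly three times female
#' rates and a working-age peak, giving an overall rate of about 1 per
#' 10,000 person-years. With default stratum populations of 300-1000 people
#' these produce area-year expected counts near 1 and heavy zero inflation,
#' the regime the hurdle model targets.
#'
#' @return Data frame with columns `age_band`, `sex`, `rate`.
#' @export
default_baseline_rates <- function() {
  age_bands <- c("10-19", "20-29", "30-39", "40-49",
                 "50-59", "60-69", "70-79", "80+")
  male <- c(5, 15, 18, 20, 16, 11, 10, 12) * 1e-5
  female <- c(2, 5, 6, 7, 6, 4, 3, 4) * 1e-5
  data.frame(age_band = rep(age_bands, 2L),
             sex = rep(c("male", "female"), each = 8L),
             rate = c(male, female),
             stringsAsFactors = FALSE)
}

#' Simulate a stratified panel from the hurdle model
#'
#' Generates a complete (area, year, age-band, sex) panel with known ground
#' truth, mirroring the model's own data-generating mechanism:
#' 1. stratum populations drawn uniformly in `pop_range`;
#' 2. stratum expected deaths = population x baseline rate; area-year
#'    expected count `E(i, t)` is their sum;
#' 3. per (area, year), occurrence `z ~ Bernoulli(pi)` and, if `z = 1`, a
#'    total drawn from the zero-truncated Poisson with rate `mu`, where
#'    `(pi, mu)` come from [linear_predictors()] under `params`;
#' 4. the total is allocated to strata by a multinomial draw with
#'    probabilities proportional to stratum expected deaths, so indirect
#'    standardisation of the simulated panel is self-consistent.
#'
#' @param graph An [area_graph()].
#' @param covariates `n_areas x K` standardised covariate matrix.
#' @param params An [hp_params()] giving the ground-truth latent state.
#' @param baseline_rates Data frame `age_band`, `sex`, `rate` (default
#'   [default_baseline_rates()]).
#' @param pop_range Interval of stratum population sizes (default
#'   `c(300, 1000)`, i.e. areas of roughly 5,000-15,000 people over 16
#'   strata).
#' @param n_years Number of years.
#' @param seed Integer seed; the output is a pure function of the inputs.
#' @param start_year First calendar year label (default 2002).
#' @param pi_fixed Optional occurrence probability overriding the model's
#'   `pi` everywhere (e.g. 1 to force the hurdle gate open, 0 to close it).
#' @return List with elements `panel` (a [stratified_panel()]), `truth`
#'   (list `params`, `rr_surface` with the exact area-year relative-risk
#'   surface `exp(x' beta_p + b + gamma + phi_t + psi)`, plus the realised
#'   `E` matrix), and `area_ids`.
#' @export
simulate_dataset <- function(graph, covariates, params,
                             baseline_rates = default_baseline_rates(),
                             pop_range = c(300, 1000),
                             n_years, seed, start_year = 2002L,
                             pi_fixed = NULL) {
  stopifnot(inherits(graph, "area_graph"), inherits(params, "hp_params"))
  n <- graph$n_areas
  covariates <- as.matrix(covariates)
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 1L) stop("`n_years` must be positive", call. = FALSE)
  if (nrow(covariates) != n || length(params$u) != n ||
      length(params$gamma) != n_years) {
    stop("dimension mismatch between graph, covariates, params and n_years",
         call. = FALSE)
  }
  if (length(pop_range) != 2L || any(pop_range <= 0) || pop_range[1L] > pop_range[2L]) {
    stop("`pop_range` must be a positive interval", call. = FALSE)
  }
  if (!all(c("age_band", "sex", "rate") %in% names(baseline_rates)) ||
      any(baseline_rates$rate <= 0)) {
    stop("`baseline_rates` must have positive rates per (age_band, sex)", call. = FALSE)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  n_strata <- nrow(baseline_rates)
  area_ids <- sprintf("A%04d", seq_len(n))
  years <- start_year + seq_len(n_years) - 1L
  # rows: stratum within area-year; full grid in (area, year, stratum) order
  grid <- expand.grid(stratum = seq_len(n_strata), year = years,
                      area = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  pop <- stats::runif(nrow(grid), pop_range[1L], pop_range[2L])
  exp_strat <- pop * baseline_rates$rate[grid$stratum]
  # grid rows are ordered area-major, then year, then stratum (fastest)
  E <- t(apply(array(exp_strat, dim = c(n_strata, n_years, n)), c(2L, 3L), sum))
  dimnames(E) <- list(area_ids, years)

  lp <- linear_predictors(params, covariates, E)
  pi_mat <- if (is.null(pi_fixed)) lp$pi else matrix(pi_fixed, n, n_years)
  mu_mat <- lp$mu

  z <- matrix(stats::rbinom(n * n_years, 1L, pi_mat), n, n_years)
  totals <- matrix(0L, n, n_years)
  idx_pos <- which(z == 1L)
  if (length(idx_pos)) {
    totals[idx_pos] <- rztpois(mu_mat[idx_pos], size = length(idx_pos))
  }

  deaths <- integer(nrow(grid))
  for (cell in which(totals > 0L)) {
    i <- (cell - 1L) %% n + 1L
    t_ <- (cell - 1L) %/% n + 1L
    rows <- ((i - 1L) * n_years + (t_ - 1L)) * n_strata + seq_len(n_strata)
    w <- exp_strat[rows]
    deaths[rows] <- as.integer(stats::rmultinom(1L, totals[i, t_], w / sum(w)))
  }

  panel <- stratified_panel(data.frame(
    area_id = area_ids[grid$area],
    year = grid$year,
    age_band = baseline_rates$age_band[grid$stratum],
    sex = baseline_rates$sex[grid$stratum],
    population = pop,
    deaths = deaths,
    stringsAsFactors = FALSE))

  b <- spatial_effect(params)
  tt <- params$gamma + params$phi_t
  rr <- exp(as.numeric(covariates %*% params$beta_p) + b +
              matrix(tt, n, n_years, byrow = TRUE) + params$psi)
  dimnames(rr) <- list(area_ids, years)

  list(panel = panel,
       truth = list(params = params, rr_surface = rr, E = E,
                    pi = pi_mat, mu = mu_mat, totals = totals),
       area_ids = area_ids)
}
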