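# shared fixture builders (all data generated in code)

# the worked standardisation example: 2 areas, 1 year, strata young/old
toy_panel <- function() {
  stratified_panel(data.frame(
    area_id = rep(c("a1", "a2"), each = 2L),
    year = 2000L,
    age_band = rep(c("young", "old"), 2L),
    sex = "all",
    population = c(100, 200, 300, 400),
    deaths = c(1L, 4L, 2L, 3L)))
}

# hand-built posterior container for summary-level tests: every latent field
# supplied as a draws matrix (rows = draws); split into 2 equal chains
fake_samples <- function(beta_p, b, gamma, phi_t, psi,
                         beta_b = beta_p * 0, alpha_p = NULL, alpha_b = NULL,
                         area_ids = NULL, years = NULL, covnames = NULL) {
  S <- nrow(b)
  n <- ncol(b); T_ <- ncol(gamma); K <- ncol(beta_p)
  if (is.null(alpha_p)) alpha_p <- matrix(0, S, 1L)
  if (is.null(alpha_b)) alpha_b <- matrix(0, S, 1L)
  if (is.null(covnames)) covnames <- paste0("cov", seq_len(K))
  if (is.null(area_ids)) area_ids <- sprintf("A%04d", seq_len(n))
  if (is.null(years)) years <- seq_len(T_)
  fixed <- cbind(alpha_p, alpha_b, beta_p, beta_b)
  colnames(fixed) <- c("alpha_p", "alpha_b",
                       paste0("beta_p_", covnames), paste0("beta_b_", covnames))
  hyper <- matrix(1, S, 8L,
                  dimnames = list(NULL, c("sigma_b", "phi", "sigma_g", "sigma_f",
                                          "sigma_psi", "delta_s", "delta_t",
                                          "delta_st")))
  stopifnot(S %% 2L == 0L)
  half <- S / 2L
  split_rows <- list(seq_len(half), half + seq_len(half))
  chains <- lapply(split_rows, function(r) {
    list(fixed = fixed[r, , drop = FALSE], b = b[r, , drop = FALSE],
         gamma = gamma[r, , drop = FALSE], phi_t = phi_t[r, , drop = FALSE],
         psi = psi[r, , drop = FALSE], hyper = hyper[r, , drop = FALSE],
         loglik = rep(0, length(r)))
  })
  structure(list(chains = chains,
                 dims = list(n_areas = n, n_years = T_, K = K,
                             area_ids = area_ids, years = years,
                             covariate_names = covnames),
                 spec = NULL,
                 meta = list(seed = 0L, n_chains = 2L)),
            class = "hp_samples")
}

# dense constrained pseudo-inverse diagonal: independent oracle for scaling
dense_marginal_vars <- function(Qd) {
  eg <- eigen(Qd, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  rowSums(sweep(eg$vectors[, pos, drop = FALSE]^2, 2L, eg$values[pos], "/"))
}

# Moran's I by the direct double sum, with moments under the normal null
moran_oracle <- function(x, edges, n) {
  W <- matrix(0, n, n)
  W[edges] <- 1
  W[edges[, 2:1, drop = FALSE]] <- 1
  z <- x - mean(x)
  S0 <- sum(W)
  I <- (n / S0) * sum(W * outer(z, z)) / sum(z^2)
  S1 <- 2 * S0  # symmetric 0/1 weights: sum (w_ij + w_ji)^2 / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  EI <- -1 / (n - 1)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  list(I = I, EI = EI, sd = sqrt(VI))
}
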