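#' Intrinsic GMRF precision structures
#'
#' Machinery shared by the spatial (ICAR / BYM2) and temporal (first-order
#' random walk) priors: the sparse structure matrix `Q`, its rank deficiency
#' (one per connected component for ICAR, one for RW1), and the
#' generalised-variance scaling constant. The scaling is the geometric mean
#' of the marginal variances of the sum-to-zero-constrained intrinsic field
#' (equivalently of `diag(Q^+)`), so that a scaled field `u` with precision
#' `scaling * Q` has typical marginal variance 1 and its standard-deviation
#' hyperparameter is interpretable on a common scale.
#'
#' @name precision_structure
NULL

new_precision_structure <- function(Q, rank_deficiency, scaling, isolated = integer()) {
  structure(list(Q = Q, rank_deficiency = as.integer(rank_deficiency),
                 scaling = scaling, isolated = as.integer(isolated)),
            class = "precision_structure")
}

#' @export
print.precision_structure <- function(x, ...) {
  cat(sprintf("precision_structure: %d x %d, rank deficiency %d, scaling %.6g\n",
              nrow(x$Q), ncol(x$Q), x$rank_deficiency, x$scaling))
  invisible(x)
}

# geometric-mean marginal variance of the constrained intrinsic field,
# computed per connected component by dense eigendecomposition
gmrf_scaling <- function(Q, component) {
  n <- nrow(Q)
  mv <- rep(NA_real_, n)
  for (cc in unique(component)) {
    nodes <- which(component == cc)
    if (length(nodes) < 2L) next  # isolated node: no structured variance
    Qc <- as.matrix(Q[nodes, nodes, drop = FALSE])
    eg <- eigen(Qc, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    Vi <- eg$vectors[, pos, drop = FALSE]
    mv[nodes] <- rowSums(sweep(Vi^2, 2L, eg$values[pos], "/"))
  }
  ok <- !is.na(mv)
  if (!any(ok)) return(1)  # edgeless graph: no structured field at all
  exp(mean(log(mv[ok])))
}

#' ICAR precision structure of an area graph
#'
#' `Q = D - W` (degree matrix minus adjacency). Rows sum to zero; the rank
#' deficiency equals the number of connected components. Isolated areas
#' (degree zero) carry no structured spatial effect and are recorded in the
#' `isolated` field; the BYM2 prior gives them purely unstructured variance.
#'
#' @param graph An [area_graph()].
#' @return A `precision_structure`.
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n_areas
  deg <- graph_degrees(graph)
  if (nrow(graph$edges) > 0L) {
    Q <- Matrix::sparseMatrix(
      i = c(seq_len(n), graph$edges[, 1L], graph$edges[, 2L]),
      j = c(seq_len(n), graph$edges[, 2L], graph$edges[, 1L]),
      x = c(as.numeric(deg), rep(-1, 2L * nrow(graph$edges))),
      dims = c(n, n))
  } else {
    Q <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  }
  isolated <- which(deg == 0L)
  new_precision_structure(Q, rank_deficiency = max(graph$component),
                          scaling = gmrf_scaling(Q, graph$component),
                          isolated = isolated)
}

#' First-order random-walk precision structure
#'
#' Tridiagonal first-difference penalty over `n_years` ordered time points:
#' the quadratic form equals the sum of squared year-on-year increments. Rank
#' deficiency 1 (invariant to level shifts), scaled like the ICAR structure.
#'
#' @param n_years Number of time points (`>= 2`).
#' @return A `precision_structure`.
#' @export
rw1_precision <- function(n_years) {
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 2L) {
    stop("`n_years` must be an integer >= 2", call. = FALSE)
  }
  i <- seq_len(n_years - 1L)
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(n_years), i, i + 1L),
    j = c(seq_len(n_years), i + 1L, i),
    x = c(1, rep(2, max(0L, n_years - 2L)), 1, rep(-1, 2L * (n_years - 1L))),
    dims = c(n_years, n_years))
  new_precision_structure(Q, rank_deficiency = 1L,
                          scaling = gmrf_scaling(Q, rep(1L, n_years)))
}

#' Log-density of a constrained intrinsic GMRF
#'
#' Evaluates the improper Gaussian density of a sum-to-zero-constrained
#' intrinsic field `x` with precision `tau * scaling * Q`, using the
#' rank-adjusted generalised log-determinant (product of non-zero
#' eigenvalues). Isolated nodes are excluded; `x` must be (numerically) zero
#' there.
#'
#' @param x Field values (length `nrow(Q)`).
#' @param prec A `precision_structure`.
#' @param tau Precision multiplier (> 0).
#' @return Log-density (a scalar), up to the constrained-measure convention.
#' @export
gmrf_logdensity <- function(x, prec, tau = 1) {
  stopifnot(inherits(prec, "precision_structure"))
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  n <- nrow(prec$Q)
  if (length(x) != n) stop("`x` has wrong length", call. = FALSE)
  keep <- setdiff(seq_len(n), prec$isolated)
  if (length(prec$isolated) && any(abs(x[prec$isolated]) > 1e-12)) {
    stop("intrinsic field must be zero on isolated nodes", call. = FALSE)
  }
  Qs <- prec$scaling * as.matrix(prec$Q[keep, keep, drop = FALSE])
  ev <- eigen(Qs, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev > max(ev, 1) * 1e-10
  rank_eff <- sum(pos)
  quad <- as.numeric(t(x[keep]) %*% Qs %*% x[keep])
  0.5 * rank_eff * log(tau) + 0.5 * sum(log(ev[pos])) -
    0.5 * rank_eff * log(2 * pi) - 0.5 * tau * quad
}

#' Penalised-complexity prior for a precision parameter
#'
#' The PC prior shrinking a random-effect standard deviation `sigma =
#' tau^-1/2` towards zero is exponential on `sigma` with rate `lambda =
#' -log(alpha) / u`, i.e. it encodes the tail statement `P(sigma > u) =
#' alpha`. Expressed as a density of the precision `tau` it is the type-2
#' Gumbel `lambda/2 * tau^-3/2 * exp(-lambda / sqrt(tau))`.
#'
#' @param tau Precision value(s), > 0.
#' @param u,alpha Tail-statement parameters (`u > 0`, `alpha` in (0,1)).
#' @return Log prior density with respect to `tau`.
#' @export
pc_prec_logprior <- function(tau, u = 1, alpha = 0.01) {
  if (u <= 0 || alpha <= 0 || alpha >= 1) {
    stop("need u > 0 and alpha in (0, 1)", call. = FALSE)
  }
  if (any(tau <= 0)) stop("`tau` must be positive", call. = FALSE)
  lambda <- -log(alpha) / u
  log(lambda / 2) - 1.5 * log(tau) - lambda / sqrt(tau)
}

#' @rdname pc_prec_logprior
#' @return `pc_prec_median` returns the prior median precision (the point at
#'   which half the prior mass on `sigma` lies above).
#' @export
pc_prec_median <- function(u = 1, alpha = 0.01) {
  lambda <- -log(alpha) / u
  (log(2) / lambda)^-2
}

#' Penalised-complexity prior for the BYM2 mixing parameter
#'
#' The BYM2 spatial effect mixes a scaled ICAR field and white noise:
#' `b = sigma * (sqrt(1 - phi) * v + sqrt(phi) * u)`. The PC prior on the
#' mixing weight `phi` penalises the Kullback-Leibler distance from the base
#' model `phi = 0` (pure white noise). With `gamma_i` the eigenvalues of the
#' constrained scaled-ICAR covariance, `KLD(phi) = 0.5 * sum(phi * (gamma_i
#' - 1) - log(1 + phi * (gamma_i - 1)))` and the prior is a (truncated)
#' exponential on the distance `d(phi) = sqrt(2 KLD)`, with its rate chosen
#' so that `P(phi < u) = alpha`.
#'
#' Because the distance depends on the graph, the prior is returned as a
#' lookup table (dense grid of `phi` values with log-densities) that the
#' sampler interpolates linearly.
#'
#' @param prec An ICAR `precision_structure` (from [icar_precision()]).
#' @param component Connected-component labels of the graph.
#' @param u,alpha Tail-statement parameters: `P(phi < u) = alpha`
#'   (default `u = 0.5`, `alpha = 0.5`).
#' @param n_grid Grid resolution.
#' @return List with `phi` (grid) and `logprior` (log densities w.r.t. phi).
#' @export
pc_phi_prior <- function(prec, component, u = 0.5, alpha = 0.5, n_grid = 201L) {
  stopifnot(inherits(prec, "precision_structure"))
  n <- nrow(prec$Q)
  keep <- setdiff(seq_len(n), prec$isolated)
  # eigenvalues of the constrained scaled-ICAR covariance (gamma_i);
  # null directions contribute gamma = 0
  gam <- numeric(0)
  for (cc in unique(component[keep])) {
    nodes <- intersect(which(component == cc), keep)
    Qc <- prec$scaling * as.matrix(prec$Q[nodes, nodes, drop = FALSE])
    ev <- eigen(Qc, symmetric = TRUE, only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-10
    gam <- c(gam, 1 / ev[pos], rep(0, sum(!pos)))
  }
  kld <- function(phi) {
    0.5 * sum(phi * (gam - 1) - log1p(phi * (gam - 1)))
  }
  dist <- function(phi) sqrt(2 * pmax(0, vapply(phi, kld, 0)))
  phi_grid <- seq(0, 1 - 1e-6, length.out = n_grid)
  d <- dist(phi_grid)
  d_max <- d[n_grid]
  d_u <- dist(u)
  # truncated-exponential cdf ratio; lambda -> 0 limit is d(u)/d(max)
  fcdf <- function(lambda) {
    if (abs(lambda) < 1e-8) return(d_u / d_max)
    expm1(-lambda * d_u) / expm1(-lambda * d_max)
  }
  g <- function(lambda) fcdf(lambda) - alpha
  lambda <- tryCatch(stats::uniroot(g, c(-50, 50), tol = 1e-10)$root,
                     error = function(e) 0)
  dprime <- c(diff(d) / diff(phi_grid))
  dprime <- c(dprime[1L], (dprime[-1L] + dprime[-length(dprime)]) / 2, dprime[length(dprime)])
  dprime <- pmax(dprime, 1e-12)
  if (abs(lambda) < 1e-8) {
    logp <- log(dprime) - log(d_max)
  } else {
    logp <- log(abs(lambda)) - lambda * d - log(abs(expm1(-lambda * d_max))) + log(dprime)
  }
  list(phi = phi_grid, logprior = logp, lambda = lambda)
}
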