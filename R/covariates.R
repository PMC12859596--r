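#' Column-standardise a covariate matrix
#'
#' Centres each column to sample mean 0 and scales to sample standard
#' deviation 1, mirroring the convention that area-level socio-environmental
#' scores enter the model standardised so regression coefficients are
#' per-standard-deviation effects.
#'
#' @param x Numeric matrix (areas x covariates), no missing values.
#' @return Matrix of the same shape with standardised columns.
#' @export
standardise_covariates <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("covariates must not contain missing values", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least two areas to standardise", call. = FALSE)
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("cannot standardise constant covariate column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scale(x, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Simulate spatially autocorrelated standardised covariates
#'
#' Draws `K` independent columns from a proper conditional-autoregressive
#' (CAR) Gaussian field on the area graph, with joint precision
#' `D - spatial_corr * W` (degree matrix minus scaled adjacency), then
#' standardises each column. `spatial_corr = 0` gives standardised white
#' noise; values near 1 give strongly smoothed fields, emulating area-level
#' scores such as deprivation indices that vary smoothly in space.
#'
#' @param graph An [area_graph()].
#' @param K Number of covariate columns (default 7).
#' @param spatial_corr CAR autocorrelation parameter in `[0, 1)`.
#' @param seed Integer seed; output is a pure function of the inputs.
#' @param names Optional column names (default `cov1..covK`).
#' @return Numeric matrix `n_areas x K`, each column mean 0 and sd 1.
#' @export
simulate_covariates <- function(graph, K = 7L, spatial_corr = 0.9, seed = 1L,
                                names = NULL) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n_areas
  if (n < 2L) stop("graph must contain at least two areas", call. = FALSE)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be a positive integer", call. = FALSE)
  if (!is.numeric(spatial_corr) || length(spatial_corr) != 1L ||
      spatial_corr < 0 || spatial_corr >= 1) {
    stop("`spatial_corr` must lie in [0, 1)", call. = FALSE)
  }
  deg <- graph_degrees(graph)
  # proper CAR precision; isolated nodes (degree 0) fall back to unit precision
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(n), graph$edges[, 1L], graph$edges[, 2L]),
    j = c(seq_len(n), graph$edges[, 2L], graph$edges[, 1L]),
    x = c(pmax(deg, 1L), rep(-spatial_corr, 2L * nrow(graph$edges))),
    dims = c(n, n), symmetric = FALSE
  )
  R <- chol(as.matrix(Q))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * K), n, K)
  x <- backsolve(R, z)
  if (is.null(names)) names <- paste0("cov", seq_len(K))
  if (length(names) != K) stop("`names` must have length K", call. = FALSE)
  colnames(x) <- names
  standardise_covariates(x)
}
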