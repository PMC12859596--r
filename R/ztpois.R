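#' Zero-truncated Poisson distribution
#'
#' The positive-count component of the hurdle model is a Poisson distribution
#' conditioned on being at least 1: pmf `mu^k e^-mu / (k! (1 - e^-mu))` for
#' `k >= 1`. Its mean is `mu / (1 - e^-mu)`.
#'
#' @param x Vector of non-negative integers (density is 0 below 1).
#' @param mu Poisson rate parameter(s), strictly positive.
#' @param log If `TRUE`, return log-probabilities.
#' @return `dztpois` returns (log-)probabilities; `rztpois` returns integer
#'   draws `>= 1`; `ztpois_mean` returns the analytic mean.
#' @name ztpois
NULL

#' @rdname ztpois
#' @export
dztpois <- function(x, mu, log = FALSE) {
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  # log(1 - e^-mu) via expm1 for small mu
  lp <- stats::dpois(x, mu, log = TRUE) - log(-expm1(-mu))
  lp[x < 1] <- -Inf
  if (log) lp else exp(lp)
}

#' @rdname ztpois
#' @param size Number of draws.
#' @param seed Optional integer seed; when supplied the draw is a pure
#'   function of `(mu, size, seed)`.
#' @export
rztpois <- function(mu, size, seed = NULL) {
  if (length(mu) != 1L && length(mu) != size) {
    stop("`mu` must have length 1 or `size`", call. = FALSE)
  }
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("`size` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
  }
  # inverse-cdf draw restricted to the truncated support: exact and vectorised
  p0 <- stats::ppois(0, mu)
  u <- stats::runif(size)
  as.integer(stats::qpois(p0 + u * (1 - p0), mu))
}

#' @rdname ztpois
#' @export
ztpois_mean <- function(mu) {
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  mu / -expm1(-mu)
}
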