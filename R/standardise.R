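#' Pooled age-sex reference rates
#'
#' Internal indirect standardisation: the reference rate for each
#' (age-band, sex) stratum is total deaths over total person-years pooled
#' across every area and year in the panel, i.e. the whole study region and
#' period acts as its own reference population.
#'
#' @param panel A [stratified_panel()].
#' @return Data frame of class `reference_rates` with columns `age_band`,
#'   `sex`, `rate` (deaths per person-year).
#' @export
compute_reference_rates <- function(panel) {
  stopifnot(inherits(panel, "stratified_panel"))
  agg <- stats::aggregate(cbind(deaths, population) ~ age_band + sex,
                          data = panel, FUN = sum)
  if (any(agg$population <= 0)) {
    bad <- agg[agg$population <= 0, , drop = FALSE][1L, ]
    stop(sprintf("stratum (age band '%s', sex '%s') has zero pooled population",
                 bad$age_band, bad$sex), call. = FALSE)
  }
  out <- data.frame(age_band = agg$age_band, sex = agg$sex,
                    rate = agg$deaths / agg$population,
                    stringsAsFactors = FALSE)
  out <- out[order(out$age_band, out$sex), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reference_rates", "data.frame")
  out
}

#' Indirectly standardised expected counts
#'
#' Applies stratum-specific reference rates to each area-year's population to
#' obtain the expected count `E(i, t) = sum_strata population * rate`, the
#' offset of the count component. With internally computed rates
#' ([compute_reference_rates()]), the expected counts conserve the panel
#' total: `sum(E) == sum(deaths)`.
#'
#' @param panel A [stratified_panel()].
#' @param rates A `reference_rates` table covering every stratum in `panel`.
#' @return Data frame of class `expected_counts` with columns `area_id`,
#'   `year`, `expected`, sorted by area then year.
#' @export
compute_expected_counts <- function(panel, rates) {
  stopifnot(inherits(panel, "stratified_panel"))
  if (!all(c("age_band", "sex", "rate") %in% names(rates))) {
    stop("`rates` must have columns age_band, sex, rate", call. = FALSE)
  }
  key_p <- paste(panel$age_band, panel$sex, sep = "\r")
  key_r <- paste(rates$age_band, rates$sex, sep = "\r")
  idx <- match(key_p, key_r)
  if (anyNA(idx)) {
    bad <- panel[is.na(idx), , drop = FALSE][1L, ]
    stop(sprintf("no reference rate for stratum (age band '%s', sex '%s')",
                 bad$age_band, bad$sex), call. = FALSE)
  }
  contrib <- panel$population * rates$rate[idx]
  agg <- stats::aggregate(contrib, by = list(area_id = panel$area_id, year = panel$year),
                          FUN = sum)
  names(agg)[3L] <- "expected"
  agg <- agg[order(agg$area_id, agg$year), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("expected_counts", "data.frame")
  agg
}

# E as an areas x years matrix aligned with sorted area_ids / years
expected_matrix <- function(expected, area_ids, years) {
  key <- paste(expected$area_id, expected$year, sep = "\r")
  grid <- expand.grid(area_id = area_ids, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(grid$area_id, grid$year, sep = "\r"), key)
  if (anyNA(idx)) stop("expected counts do not cover the full area-year grid", call. = FALSE)
  matrix(expected$expected[idx], nrow = length(area_ids),
         dimnames = list(area_ids, years))
}
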