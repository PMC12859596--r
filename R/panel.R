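#' Stratified area-year panel of counts and populations
#'
#' The raw observational unit: event counts and person-year populations per
#' (area, year, age-band, sex) stratum, in long format. The default
#' stratification is 8 ten-year age bands by 2 sexes. Every (area, year) must
#' carry the complete stratum grid so that standardisation and the model's
#' space-time index never silently drop cells.
#'
#' @param data Data frame with columns `area_id` (character), `year`
#'   (integer), `age_band`, `sex`, `population` (non-negative numeric) and
#'   `deaths` (non-negative integer, elementwise `<= population`).
#' @return The validated data frame with class `stratified_panel` and
#'   attributes `area_ids`, `years`, `age_bands`, `sexes` (sorted unique
#'   levels defining the index grid).
#' @export
stratified_panel <- function(data) {
  req <- c("area_id", "year", "age_band", "sex", "population", "deaths")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[req]
  data$area_id <- as.character(data$area_id)
  data$year <- as.integer(data$year)
  data$age_band <- as.character(data$age_band)
  data$sex <- as.character(data$sex)
  if (anyNA(data)) stop("panel contains missing values", call. = FALSE)
  if (any(data$population < 0)) stop("populations must be non-negative", call. = FALSE)
  if (any(data$deaths < 0) || any(data$deaths != round(data$deaths))) {
    stop("deaths must be non-negative integers", call. = FALSE)
  }
  if (any(data$deaths > data$population)) {
    stop("deaths exceed population in some strata", call. = FALSE)
  }
  key <- paste(data$area_id, data$year, data$age_band, data$sex, sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate stratum row: area '%s', year %d, age band '%s', sex '%s'",
                 d$area_id, d$year, d$age_band, d$sex), call. = FALSE)
  }
  area_ids <- sort(unique(data$area_id))
  years <- sort(unique(data$year))
  age_bands <- sort(unique(data$age_band))
  sexes <- sort(unique(data$sex))
  n_expected <- length(area_ids) * length(years) * length(age_bands) * length(sexes)
  if (nrow(data) != n_expected) {
    grid <- expand.grid(area_id = area_ids, year = years, age_band = age_bands,
                        sex = sexes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gkey <- paste(grid$area_id, grid$year, grid$age_band, grid$sex, sep = "\r")
    missing_key <- setdiff(gkey, key)[1L]
    parts <- strsplit(missing_key, "\r", fixed = TRUE)[[1L]]
    stop(sprintf("incomplete stratum grid: missing area '%s', year %s, age band '%s', sex '%s'",
                 parts[1L], parts[2L], parts[3L], parts[4L]), call. = FALSE)
  }
  data <- data[order(data$area_id, data$year, data$age_band, data$sex), , drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            area_ids = area_ids, years = years,
            age_bands = age_bands, sexes = sexes,
            class = c("stratified_panel", "data.frame"))
}

#' @export
print.stratified_panel <- function(x, ...) {
  cat(sprintf(
    "stratified_panel: %d areas x %d years x %d age bands x %d sexes (%d rows)\n",
    length(attr(x, "area_ids")), length(attr(x, "years")),
    length(attr(x, "age_bands")), length(attr(x, "sexes")), nrow(x)))
  cat(sprintf("  total deaths %d, total person-years %.0f, zero area-years %.1f%%\n",
              sum(x$deaths), sum(x$population),
              100 * mean(panel_totals(x)$deaths == 0)))
  invisible(x)
}

#' Collapse a panel to per-(area, year) totals
#'
#' @param panel A [stratified_panel()].
#' @return Data frame with columns `area_id`, `year`, `deaths` (total over
#'   strata), sorted by area then year.
#' @export
panel_totals <- function(panel) {
  stopifnot(inherits(panel, "stratified_panel"))
  agg <- stats::aggregate(deaths ~ area_id + year, data = panel, FUN = sum)
  agg <- agg[order(agg$area_id, agg$year), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
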