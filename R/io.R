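#' Read and write package data files
#'
#' All tabular inputs and outputs are RFC-4180 CSV with a header row; the
#' area graph is a plain-text edge list ([write_area_graph()]). Area ids are
#' opaque strings; internal indices follow sorted area-id order.
#'
#' @name hpmap_io
NULL

#' @rdname hpmap_io
#' @param panel A [stratified_panel()].
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "stratified_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname hpmap_io
#' @export
read_panel <- function(path) {
  stratified_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname hpmap_io
#' @param covariates Numeric matrix of covariates with one row per area.
#' @param area_ids Character vector of area ids labelling the rows.
#' @export
write_covariates <- function(covariates, area_ids, path) {
  covariates <- as.matrix(covariates)
  stopifnot(length(area_ids) == nrow(covariates))
  df <- data.frame(area_id = as.character(area_ids), covariates,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname hpmap_io
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "area_id") {
    stop("covariate file must start with an `area_id` column", call. = FALSE)
  }
  if (anyDuplicated(df$area_id)) {
    stop("duplicate area ids in covariate file", call. = FALSE)
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(x) || anyNA(x)) {
    stop("covariate columns must be numeric with no missing values", call. = FALSE)
  }
  rownames(x) <- df$area_id
  x <- x[order(df$area_id), , drop = FALSE]
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  if (any(abs(mu) > 1e-6) || any(abs(s - 1) > 1e-6)) {
    warning("covariates were not standardised on input; re-standardising")
    rn <- rownames(x)
    x <- standardise_covariates(x)
    rownames(x) <- rn
  }
  x
}

#' @rdname hpmap_io
#' @param expected An `expected_counts` data frame.
#' @export
write_expected <- function(expected, path) {
  utils::write.csv(as.data.frame(expected), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a complete model dataset
#'
#' Loads the stratified panel, the area graph and the covariate table, and
#' cross-validates them: the panel must carry a complete stratum grid (the
#' panel reader errors naming any missing key), the graph must have exactly
#' one node per panel area (nodes indexed in sorted area-id order), and the
#' covariate table must cover exactly the panel's areas. Covariates are
#' re-standardised on load (with a warning) if the stored columns are not
#' already standard.
#'
#' @param counts_path Panel CSV path.
#' @param graph_path Edge-list path.
#' @param covariates_path Covariates CSV path.
#' @return List with `panel`, `graph`, `covariates` (matrix, rows in sorted
#'   area-id order), `area_ids`, `years`.
#' @export
read_dataset <- function(counts_path, graph_path, covariates_path) {
  panel <- read_panel(counts_path)
  graph <- read_area_graph(graph_path)
  covariates <- read_covariates(covariates_path)
  area_ids <- attr(panel, "area_ids")
  if (graph$n_areas != length(area_ids)) {
    stop(sprintf("graph has %d areas but panel has %d",
                 graph$n_areas, length(area_ids)), call. = FALSE)
  }
  unknown <- setdiff(rownames(covariates), area_ids)
  if (length(unknown)) {
    stop("covariate file contains unknown area id(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  missing_ids <- setdiff(area_ids, rownames(covariates))
  if (length(missing_ids)) {
    stop("covariate file is missing area id(s): ",
         paste(utils::head(missing_ids, 3L), collapse = ", "), call. = FALSE)
  }
  list(panel = panel, graph = graph,
       covariates = covariates[area_ids, , drop = FALSE],
       area_ids = area_ids, years = attr(panel, "years"))
}

#' Run configuration
#'
#' Flat `key = value` text file (one pair per line; `#` comments allowed).
#' Recognised keys: `counts`, `graph`, `covariates`, `out_dir` (paths);
#' `chains`, `iters`, `warmup`, `thin`, `seed`, `n_percentiles` (integers);
#' `cri_level`, `pc_u`, `pc_alpha`, `phi_u`, `phi_alpha` (reals);
#' `include_spatial`, `include_temporal`, `include_interaction`,
#' `share_scales_free` (true/false).
#'
#' @param path Config file path.
#' @return Named list of typed values with defaults filled in, class
#'   `hp_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) {
    stop("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]],
         call. = FALSE)
  }
  vals <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  as_run_config(as.list(vals))
}

#' @rdname read_run_config
#' @param config Named list of (possibly character) config values.
#' @export
as_run_config <- function(config) {
  defaults <- list(counts = NULL, graph = NULL, covariates = NULL,
                   out_dir = "hpmap_out",
                   chains = 4L, iters = 5000L, warmup = 2500L, thin = 1L,
                   seed = 1L, n_percentiles = 100L, cri_level = 0.95,
                   pc_u = 1, pc_alpha = 0.01, phi_u = 0.5, phi_alpha = 0.5,
                   include_spatial = TRUE, include_temporal = TRUE,
                   include_interaction = TRUE, share_scales_free = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- defaults
  ints <- c("chains", "iters", "warmup", "thin", "seed", "n_percentiles")
  nums <- c("cri_level", "pc_u", "pc_alpha", "phi_u", "phi_alpha")
  bools <- c("include_spatial", "include_temporal", "include_interaction",
             "share_scales_free")
  for (k in names(config)) {
    v <- config[[k]]
    out[[k]] <-
      if (k %in% ints) as.integer(v)
      else if (k %in% nums) as.numeric(v)
      else if (k %in% bools) tolower(as.character(v)) %in% c("true", "1", "yes")
      else as.character(v)
  }
  for (k in c("counts", "graph", "covariates")) {
    if (is.null(out[[k]])) stop("config is missing required key: ", k, call. = FALSE)
    if (!file.exists(out[[k]])) {
      stop("config path does not exist: ", k, " = ", out[[k]], call. = FALSE)
    }
  }
  if (is.na(out$seed) || out$seed < 0L) {
    stop("`seed` must be a non-negative integer", call. = FALSE)
  }
  if (!is.finite(out$cri_level) || out$cri_level <= 0 || out$cri_level >= 1) {
    stop("`cri_level` must lie in (0, 1)", call. = FALSE)
  }
  structure(out, class = "hp_run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  keep <- !vapply(config, is.null, TRUE)
  vals <- vapply(unclass(config)[keep], function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 15)
  }, "")
  writeLines(paste(names(vals), "=", vals), path)
  invisible(path)
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[%s] starting", name))
  out <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full analysis pipeline
#'
#' Standardisation, model fitting, convergence diagnostics and all posterior
#' summaries in one call, writing tidy CSV tables and a JSON manifest to the
#' output directory. The run is a pure function of the config (including the
#' seed): re-running with the same config yields byte-identical summary
#' tables.
#'
#' Outputs: `expected_counts.csv`, `rr_year.csv`, `rr_area.csv`,
#' `rr_area_year.csv` (with evidence categories), `covariate_effects.csv`
#' (both components), `variance_shares.csv`, `profile.csv`,
#' `diagnostics.csv`, `manifest.json`.
#'
#' @param config An `hp_run_config` (or a path to a config file, or a plain
#'   named list).
#' @return Invisibly, a list with the fitted `samples`, `diagnostics` and
#'   the output directory. Fails with an informative error if any stage
#'   fails; the manifest records whether diagnostics passed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "hp_run_config")) config <- as_run_config(config)
  if (config$chains < 2L) {
    stop("`chains` must be at least 2 (convergence diagnostics require it)",
         call. = FALSE)
  }
  ds <- stage("read", read_dataset(config$counts, config$graph, config$covariates))
  std <- stage("standardise", {
    rates <- compute_reference_rates(ds$panel)
    expected <- compute_expected_counts(ds$panel, rates)
    if (any(expected$expected <= 0)) {
      bad <- expected[expected$expected <= 0, , drop = FALSE][1L, ]
      stop(sprintf("expected count is zero for area '%s', year %d (no population?)",
                   bad$area_id, bad$year))
    }
    list(rates = rates, expected = expected)
  })
  E <- expected_matrix(std$expected, ds$area_ids, ds$years)
  totals <- panel_totals(ds$panel)
  y <- matrix(totals$deaths, nrow = length(ds$area_ids),
              ncol = length(ds$years), byrow = TRUE,
              dimnames = list(ds$area_ids, ds$years))
  spec <- hp_model_spec(include_spatial = config$include_spatial,
                        include_temporal = config$include_temporal,
                        include_interaction = config$include_interaction,
                        share_scales_free = config$share_scales_free,
                        pc_u = config$pc_u, pc_alpha = config$pc_alpha,
                        phi_u = config$phi_u, phi_alpha = config$phi_alpha)
  samples <- stage("fit", run_mcmc(y, E, ds$covariates, ds$graph, spec,
                                   n_chains = config$chains,
                                   n_iter = config$iters,
                                   n_warmup = config$warmup,
                                   thin = config$thin, seed = config$seed))
  diag_ <- stage("diagnose", convergence_diagnostics(samples))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage("summarise", {
    cri <- config$cri_level
    rr_year <- relative_risk(samples, ds$covariates, "year", cri = cri)
    rr_area <- relative_risk(samples, ds$covariates, "area", cri = cri)
    rr_ay <- relative_risk(samples, ds$covariates, "area-year", cri = cri)
    rr_area$evidence <- as.character(classify_exceedance(rr_area$exceedance))
    rr_ay$evidence <- as.character(classify_exceedance(rr_ay$exceedance))
    eff <- rbind(cbind(component = "count",
                       covariate_effects(samples, "count", cri)),
                 cbind(component = "occurrence",
                       covariate_effects(samples, "occurrence", cri)))
    shares <- variance_decomposition(samples, ds$covariates, cri)
    prof <- profile_table(rr_ay, ds$covariates, ds$area_ids,
                          n_bins = config$n_percentiles)
    utils::write.csv(std$expected, file.path(out_dir, "expected_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(rr_year, file.path(out_dir, "rr_year.csv"), row.names = FALSE)
    utils::write.csv(rr_area, file.path(out_dir, "rr_area.csv"), row.names = FALSE)
    utils::write.csv(rr_ay, file.path(out_dir, "rr_area_year.csv"), row.names = FALSE)
    utils::write.csv(eff, file.path(out_dir, "covariate_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(shares, file.path(out_dir, "variance_shares.csv"),
                     row.names = FALSE)
    utils::write.csv(prof, file.path(out_dir, "profile.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(diag_), file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)
    invisible(NULL)
  })
  manifest <- list(
    package = "hpmap",
    version = as.character(utils::packageVersion("hpmap")),
    config = unclass(config),
    dims = list(n_areas = length(ds$area_ids), n_years = length(ds$years),
                K = ncol(ds$covariates)),
    seed = config$seed,
    diagnostics_pass = isTRUE(attr(diag_, "pass")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!isTRUE(attr(diag_, "pass"))) {
    warning("convergence diagnostics did not pass; inspect diagnostics.csv")
  }
  invisible(list(samples = samples, diagnostics = diag_, out_dir = out_dir))
}
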