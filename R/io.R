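#' Write / read an ECV stack as a portable text file
#'
#' Serializes an [ecv_stack()] to a single self-describing text file: a
#' JSON header line (prefixed `#`) carrying the grid geometry, dates and
#' variable name, followed by a long-format CSV body with one row per
#' (composite, row, column) observation. Values are written at full double
#' precision, so a write-read round trip reproduces the stack exactly.
#'
#' @param stack an [ecv_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ecv_stack"))
  d <- dim(stack$values)
  header <- jsonlite::toJSON(list(
    format = "ecvagree-stack", version = 1L,
    varname = stack$varname, dims = d,
    dates = format(stack$dates, "%Y-%m-%d"),
    lat = stack$lat, lon = stack$lon, cellsize = stack$cellsize),
    auto_unbox = TRUE, digits = NA)
  idx <- expand.grid(t = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  body <- data.frame(idx,
                     value = as.vector(stack$values),
                     uncertainty = as.vector(stack$uncertainty),
                     valid = as.integer(as.vector(stack$mask)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines(paste(names(body), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(body, format_field), sep = ",")), con)
  invisible(path)
}

format_field <- function(x)
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)

#' @rdname write_stack
#' @param expect_varname optional variable name the file must carry; a
#'   mismatch (e.g. a file without the expected uncertainty-bearing
#'   variable) raises an error, since the framework is unusable without
#'   per-observation uncertainties.
#' @export
read_stack <- function(path, expect_varname = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# "))
    stop("not an ecvagree stack file (missing header): ", path)
  hd <- jsonlite::fromJSON(sub("^# ", "", first))
  if (!identical(hd$format, "ecvagree-stack"))
    stop("not an ecvagree stack file: ", path)
  if (!is.null(expect_varname) && !identical(hd$varname, expect_varname))
    stop(sprintf("expected variable '%s' but file carries '%s'",
                 expect_varname, hd$varname))
  body <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "y", "x", "value", "uncertainty", "valid")
  if (!all(need %in% names(body)))
    stop("stack file lacks required columns (value/uncertainty/valid)")
  d <- as.integer(hd$dims)
  if (nrow(body) != prod(d)) stop("stack body size does not match header dims")
  ord <- order(body$x, body$y, body$t)   # column-major (t fastest)
  arr <- function(col) array(col[ord], d)
  ecv_stack(arr(body$value), arr(body$uncertainty),
            dates = as.Date(hd$dates), lat = hd$lat, lon = hd$lon,
            mask = arr(body$valid) > 0, varname = hd$varname,
            cellsize = hd$cellsize)
}

#' Write a metrics map as a long-format CSV
#'
#' One row per pixel with latitude, longitude and every metric; the reverse
#' of no particular reader — a documented, plotting-friendly export.
#'
#' @param map a [spatial_agreement()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_map <- function(map, path) {
  stopifnot(inherits(map, "metrics_map"))
  grid <- expand.grid(y = seq_along(map$lat), x = seq_along(map$lon))
  out <- data.frame(lat = map$lat[grid$y], lon = map$lon[grid$x])
  for (m in c("n", "oa", "si", "sd", "bnc", "bns"))
    out[[m]] <- as.vector(map[[m]])[(grid$x - 1) * length(map$lat) + grid$y]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full consistency pipeline from a configuration
#'
#' Ties the stages together: read (or generate) the paired stacks, classify
#' simultaneous changes at the configured threshold, and write the temporal
#' metrics series, per-pixel metrics map, monthly climatology, seasonal
#' trend table, joint threshold sweep and multi-resolution metrics to an
#' output directory, together with a provenance record (configuration hash,
#' seed, package version). Outputs are deterministic given the seed.
#'
#' @param config named list (or path to a YAML file) with fields:
#'   `lai_path`/`fapar_path` (stack files) or `scenario` (arguments for
#'   [scenario_config()]); optional `threshold` (default 50),
#'   `agg_factors` (default `c(1, 2, 4)`), `sweep_thresholds` (default
#'   `c(25, 50, 75)`), `seed` (used for the scenario when generating), and
#'   `out_dir` (required).
#' @return invisible list of the computed tables (`temporal`, `map`,
#'   `climatology`, `trend`, `sweep`, `multiscale`) and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  threshold <- config$threshold %||% 50
  lc <- NULL
  if (!is.null(config$scenario)) {
    args <- config$scenario
    if (!is.null(config$seed)) args$seed <- config$seed
    sim <- generate_scenario(do.call(scenario_config, args))
    lai <- sim$lai; fapar <- sim$fapar; lc <- sim$lc
  } else {
    if (is.null(config$lai_path) || is.null(config$fapar_path))
      stop("config must supply either a scenario or lai_path/fapar_path")
    lai <- read_stack(config$lai_path, "lai")
    fapar <- read_stack(config$fapar_path, "fapar")
  }
  pc <- paired_changes(lai, fapar)
  temporal <- temporal_agreement(pc, threshold = threshold)
  map <- spatial_agreement(pc, threshold = threshold)
  clim <- monthly_climatology(temporal)
  trend <- do.call(rbind, lapply(c("oa", "si", "sd", "bnc", "bns"),
    function(m) {
      ok <- !is.na(temporal[[m]])
      res <- if (sum(ok) >= 24)
        seasonal_mann_kendall(temporal[[m]][ok], temporal$date[ok])
      else list(s = NA, var_s = NA, z = NA, p_value = NA, trend_sign = NA)
      data.frame(metric = m, s = res$s, z = res$z, p_value = res$p_value,
                 trend_sign = res$trend_sign)
    }))
  sweep <- sweep_joint(pc, thresholds = config$sweep_thresholds %||% c(25, 50, 75))
  factors <- config$agg_factors %||% c(1, 2, 4)
  multiscale <- multiscale_agreement(lai, fapar, factors = factors, lc = lc,
                                     threshold = threshold)
  paths <- list(
    temporal = file.path(config$out_dir, "temporal_metrics.csv"),
    map = file.path(config$out_dir, "metrics_map.csv"),
    climatology = file.path(config$out_dir, "climatology.csv"),
    trend = file.path(config$out_dir, "trend_tests.csv"),
    sweep = file.path(config$out_dir, "threshold_sweep.csv"),
    multiscale = file.path(config$out_dir, "multiscale_metrics.csv"),
    provenance = file.path(config$out_dir, "provenance.json"))
  utils::write.csv(temporal, paths$temporal, row.names = FALSE)
  write_metrics_map(map, paths$map)
  utils::write.csv(clim, paths$climatology, row.names = FALSE)
  utils::write.csv(trend, paths$trend, row.names = FALSE)
  utils::write.csv(sweep, paths$sweep, row.names = FALSE)
  utils::write.csv(multiscale, paths$multiscale, row.names = FALSE)
  prov <- list(
    package = "ecvagree",
    version = as.character(utils::packageVersion("ecvagree")),
    seed = config$seed %||% NA,
    threshold = threshold,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(temporal = temporal, map = map, climatology = clim,
                 trend = trend, sweep = sweep, multiscale = multiscale,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable short hash of the configuration (order-independent at top level)
config_hash <- function(config) {
  config <- config[order(names(config))]
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  # tiny polynomial rolling hash; enough to fingerprint a run
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
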