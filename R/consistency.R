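#' Per-pixel-step change confidences for a pair of co-registered stacks
#'
#' Computes, once, the signed change and confidence level of every
#' consecutive step of both variables at every pixel, with pairwise-complete
#' masking (a step is usable only if both variables are valid at both ends).
#' Threshold sweeps and all downstream analyses reclassify these cached
#' confidences, so the confidence computation is never repeated.
#'
#' @param lai,fapar co-registered, time-aligned [ecv_stack()] objects.
#' @return object of class `paired_changes`: arrays of dimension
#'   `c(time - 1, nrow, ncol)` — `lai_delta`, `lai_conf`, `fapar_delta`,
#'   `fapar_conf`, logical `ok` — plus `dates` (start date of each step) and
#'   the grid geometry.
#' @export
paired_changes <- function(lai, fapar) {
  check_aligned(lai, fapar)
  d <- dim(lai$values)
  nt <- d[1]
  if (nt < 2) stop("need at least two composites")
  i0 <- seq_len(nt - 1)
  sl <- function(a, idx) array(a[idx, , , drop = FALSE], c(nt - 1, d[2], d[3]))
  ok <- sl(lai$mask, i0) & sl(lai$mask, i0 + 1) &
        sl(fapar$mask, i0) & sl(fapar$mask, i0 + 1)
  cl <- confidence_level(sl(lai$values, i0), sl(lai$uncertainty, i0),
                         sl(lai$values, i0 + 1), sl(lai$uncertainty, i0 + 1))
  cf <- confidence_level(sl(fapar$values, i0), sl(fapar$uncertainty, i0),
                         sl(fapar$values, i0 + 1), sl(fapar$uncertainty, i0 + 1))
  shape <- c(nt - 1, d[2], d[3])
  structure(list(
    lai_delta = array(cl$delta, shape), lai_conf = array(cl$confidence, shape),
    fapar_delta = array(cf$delta, shape), fapar_conf = array(cf$confidence, shape),
    ok = ok, dates = lai$dates[i0], lat = lai$lat, lon = lai$lon,
    cellsize = lai$cellsize), class = "paired_changes")
}

# classify cached changes at given thresholds; returns integer codes
# 1 = decrease, 2 = non-significant, 3 = increase, NA where masked
classify_codes <- function(pc, threshold = 50,
                           lai_threshold = NULL, fapar_threshold = NULL) {
  lthr <- if (is.null(lai_threshold)) threshold else lai_threshold
  fthr <- if (is.null(fapar_threshold)) threshold else fapar_threshold
  code <- function(delta, conf, thr)
    ifelse(conf > thr & delta > 0, 3L, ifelse(conf > thr & delta < 0, 1L, 2L))
  la <- code(pc$lai_delta, pc$lai_conf, lthr)
  fa <- code(pc$fapar_delta, pc$fapar_conf, fthr)
  la[!pc$ok] <- NA_integer_; fa[!pc$ok] <- NA_integer_
  list(lai = la, fapar = fa)
}

# 9-cell joint code (column-major over [lai, fapar]); NA propagates
joint_code <- function(codes) (codes$lai - 1L) * 3L + codes$fapar

table_from_joint <- function(jc) {
  cnt <- tabulate(jc[!is.na(jc)], nbins = 9L)
  m <- matrix(as.integer(cnt), 3, 3, byrow = TRUE,
              dimnames = list(lai = CHANGE_LEVELS, fapar = CHANGE_LEVELS))
  structure(m, N = sum(m), class = c("change_table", "matrix"))
}

#' Temporal (map-approach) agreement series over a region
#'
#' For each consecutive time step, classifies the simultaneous changes of all
#' region pixels valid at both ends in both variables, tabulates them into
#' one contingency table per step and derives the agreement metrics. The
#' result is a metrics time series from which short-term (climatology) and
#' long-term (trend) consistency are assessed.
#'
#' @param lai,fapar [ecv_stack()] objects, or a precomputed
#'   [paired_changes()] passed as `lai` (then `fapar` is ignored).
#' @param region optional [region_spec()]; default all pixels.
#' @param threshold confidence threshold in percent.
#' @param lai_threshold,fapar_threshold optional per-variable thresholds.
#' @return data.frame with one row per step: `date`, the metric columns of
#'   [agreement_metrics()] and `processed_fraction` (pairs tabulated over
#'   region pixel count). Steps with no valid pair carry `NA` metrics.
#' @export
temporal_agreement <- function(lai, fapar = NULL, region = NULL,
                               threshold = 50, lai_threshold = NULL,
                               fapar_threshold = NULL) {
  pc <- if (inherits(lai, "paired_changes")) lai else paired_changes(lai, fapar)
  d <- dim(pc$ok)
  member <- if (is.null(region)) matrix(TRUE, d[2], d[3]) else region$member
  if (!any(member)) stop("region membership must be non-empty")
  codes <- classify_codes(pc, threshold, lai_threshold, fapar_threshold)
  jc <- joint_code(codes)
  npix <- sum(member)
  rows <- lapply(seq_len(d[1]), function(t) {
    jt <- jc[t, , ][member]
    met <- agreement_metrics(table_from_joint(jt))
    met$processed_fraction <- met$n / npix
    met
  })
  out <- do.call(rbind, rows)
  out <- cbind(date = pc$dates, out)
  rownames(out) <- NULL
  out
}

#' Spatial (pixel-approach) agreement maps
#'
#' Classifies the full-period time series of simultaneous changes at each
#' pixel, tabulates per pixel across time and maps the agreement metrics.
#'
#' @inheritParams temporal_agreement
#' @return object of class `metrics_map`: list of `nrow x ncol` matrices
#'   `n`, `oa`, `si`, `sd`, `bnc`, `bns`, plus `lat`, `lon`.
#' @export
spatial_agreement <- function(lai, fapar = NULL, threshold = 50,
                              lai_threshold = NULL, fapar_threshold = NULL) {
  pc <- if (inherits(lai, "paired_changes")) lai else paired_changes(lai, fapar)
  d <- dim(pc$ok)
  jc <- joint_code(classify_codes(pc, threshold, lai_threshold, fapar_threshold))
  nm <- c("n", "oa", "si", "sd", "bnc", "bns")
  maps <- lapply(nm, function(x) matrix(NA_real_, d[2], d[3]))
  names(maps) <- nm
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    met <- agreement_metrics(table_from_joint(jc[, i, j]))
    for (x in nm) maps[[x]][i, j] <- met[[x]]
  }
  structure(c(maps, list(lat = pc$lat, lon = pc$lon)), class = "metrics_map")
}

#' @export
print.metrics_map <- function(x, ...) {
  cat(sprintf("<metrics_map> %d x %d grid; mean OA = %.3f\n",
              nrow(x$oa), ncol(x$oa), mean(x$oa, na.rm = TRUE)))
  invisible(x)
}

#' Monthly climatology of an agreement-metrics series
#'
#' Multi-year mean and standard deviation of each metric by calendar month;
#' composites are keyed to months by their start date.
#'
#' @param series data.frame from [temporal_agreement()] (needs a `date`
#'   column).
#' @param metrics metric columns to summarise.
#' @return data.frame with columns `month` (1-12), `metric`, `mean`, `sd`,
#'   `n_obs`. Months with no data are `NA`; a single year of data yields
#'   that year's values with `NA` dispersion where only one composite falls
#'   in a month.
#' @export
monthly_climatology <- function(series,
                                metrics = c("oa", "si", "sd", "bnc", "bns",
                                            "processed_fraction")) {
  metrics <- intersect(metrics, names(series))
  mo <- as.integer(format(as.Date(series$date), "%m"))
  out <- expand.grid(month = 1:12, metric = metrics,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$sd <- NA_real_; out$n_obs <- 0L
  for (r in seq_len(nrow(out))) {
    x <- series[[out$metric[r]]][mo == out$month[r]]
    x <- x[!is.na(x)]
    out$n_obs[r] <- length(x)
    if (length(x)) {
      out$mean[r] <- mean(x)
      out$sd[r] <- if (length(x) > 1) stats::sd(x) else NA_real_
    }
  }
  out
}

#' Seasonal Mann-Kendall trend test
#'
#' Tests for a monotonic trend in a seasonal series by computing the Kendall
#' score S within each season (calendar month by default) and summing across
#' seasons; the two-sided p-value uses the normal approximation with
#' within-season tie correction and continuity correction. Inter-season
#' covariance is not corrected for.
#'
#' @param x numeric series (NAs dropped within season).
#' @param dates composite start dates, used to assign seasons as calendar
#'   months; alternatively supply `seasons` directly.
#' @param seasons optional integer season index per observation (overrides
#'   `dates`).
#' @param alpha two-sided significance level for `trend_sign`.
#' @return list with `s` (summed Kendall score), `var_s`, `z`, `p_value`,
#'   and `trend_sign` (-1, 0, +1; 0 when not significant at `alpha`).
#' @export
seasonal_mann_kendall <- function(x, dates = NULL, seasons = NULL,
                                  alpha = 0.05) {
  if (is.null(seasons)) {
    if (is.null(dates)) stop("supply dates or seasons")
    seasons <- as.integer(format(as.Date(dates), "%m"))
  }
  stopifnot(length(seasons) == length(x))
  S <- 0; V <- 0; max_n <- 0
  for (s in unique(seasons)) {
    xs <- x[seasons == s]
    xs <- xs[!is.na(xs)]
    n <- length(xs)
    max_n <- max(max_n, n)
    if (n < 2) next
    dmat <- outer(xs, xs, "-")          # [i, j] = xs[i] - xs[j]
    S <- S + sum(sign(dmat[lower.tri(dmat)]))
    ties <- table(xs)
    V <- V + (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  }
  if (max_n < 2)
    stop("series too short: need at least two observations in some season")
  z <- if (V > 0 && S != 0) (S - sign(S)) / sqrt(V) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(s = S, var_s = V, z = z, p_value = p,
       trend_sign = if (p < alpha) sign(S) else 0)
}

#' Compare two metric maps over a stratum
#'
#' Tests for mean and distribution differences between two products' metric
#' maps over a stratum, using the Welch unequal-variance two-sample t test
#' and the two-sample Kolmogorov-Smirnov test.
#'
#' @param map_a,map_b [spatial_agreement()] results (or plain numeric
#'   vectors/matrices of a metric).
#' @param metric metric name when metric maps are supplied.
#' @param stratum optional [region_spec()] restricting the pixels compared.
#' @return list with `welch_t`, `welch_p`, `ks_d`, `ks_p`, `n_a`, `n_b`.
#' @export
compare_products <- function(map_a, map_b, metric = "oa", stratum = NULL) {
  pick <- function(m) {
    v <- if (inherits(m, "metrics_map")) m[[metric]] else m
    if (!is.null(stratum)) v <- as.matrix(v)[stratum$member]
    as.numeric(v[!is.na(v)])
  }
  a <- pick(map_a); b <- pick(map_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two valid pixels per product")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b)))) {
    wt <- list(statistic = c(t = 0), p.value = 1)  # degenerate identical maps
  } else {
    wt <- stats::t.test(a, b, var.equal = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(welch_t = unname(wt$statistic), welch_p = wt$p.value,
       ks_d = unname(ks$statistic), ks_p = ks$p.value,
       n_a = length(a), n_b = length(b))
}

#' Latitude-band zonal means of a metric map
#'
#' Area-unweighted mean of valid pixels within half-open latitude bands
#' `[lat, lat + width)` anchored at multiples of `width`.
#'
#' @param map a [spatial_agreement()] result or a numeric matrix.
#' @param lat latitudes of grid rows (taken from the map if present).
#' @param metric metric name when a metrics map is supplied.
#' @param width band width in degrees.
#' @return data.frame with `lat_lo`, `lat_hi`, `mean`, `n_pixels`; bands
#'   with no valid pixel carry `NA`.
#' @export
zonal_mean <- function(map, lat = NULL, metric = "oa", width = 1) {
  v <- if (inherits(map, "metrics_map")) map[[metric]] else as.matrix(map)
  if (is.null(lat)) {
    if (inherits(map, "metrics_map")) lat <- map$lat
    else stop("supply row latitudes")
  }
  stopifnot(length(lat) == nrow(v))
  band <- floor(lat / width) * width
  ub <- sort(unique(band))
  out <- data.frame(lat_lo = ub, lat_hi = ub + width,
                    mean = NA_real_, n_pixels = 0L)
  for (k in seq_along(ub)) {
    x <- v[band == ub[k], , drop = FALSE]
    x <- x[!is.na(x)]
    out$n_pixels[k] <- length(x)
    if (length(x)) out$mean[k] <- mean(x)
  }
  out
}
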