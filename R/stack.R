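#' Gridded ECV stack
#'
#' Container for one ECV raster time series: a `time x y x x` cube of values
#' with matching per-observation uncertainties and a validity mask, plus grid
#' geometry and composite start dates. Grids are regular lat/lon; `lat` runs
#' along the `y` dimension and `lon` along `x`.
#'
#' @param values,uncertainty numeric arrays of dimension
#'   `c(time, nrow, ncol)`; uncertainties are one-sigma half-widths in the
#'   variable's units.
#' @param dates vector of composite start dates (`Date` or coercible),
#'   strictly increasing, one per time slice.
#' @param lat,lon cell-center coordinates (length `nrow` / `ncol`). Defaults
#'   to a unit grid.
#' @param mask logical array of the same dimension as `values`; `FALSE`
#'   marks observations excluded by quality control. Defaults to
#'   `!is.na(values)`.
#' @param varname variable name tag, e.g. `"lai"` or `"fapar"`.
#' @param cellsize grid cell size in degrees (scalar). Defaults to the lat
#'   spacing, or 1 for a single-row grid.
#'
#' @return object of class `ecv_stack` (a list with the validated fields).
#' @export
ecv_stack <- function(values, uncertainty, dates,
                      lat = NULL, lon = NULL, mask = NULL,
                      varname = "ecv", cellsize = NULL) {
  values <- as.array(values); uncertainty <- as.array(uncertainty)
  if (length(dim(values)) != 3)
    stop("values must be a time x y x x array")
  if (!identical(dim(values), dim(uncertainty)))
    stop("values and uncertainty must have identical dimensions")
  d <- dim(values)
  if (length(dates) != d[1]) stop("one date per time slice required")
  dates <- as.Date(dates)
  if (any(diff(as.numeric(dates)) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(lat)) lat <- seq_len(d[2]) - 0.5
  if (is.null(lon)) lon <- seq_len(d[3]) - 0.5
  if (length(lat) != d[2] || length(lon) != d[3])
    stop("lat/lon lengths must match grid dimensions")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- array(as.logical(mask), d)
  if (any(uncertainty < 0 & mask, na.rm = TRUE))
    stop("uncertainties must be non-negative")
  if (is.null(cellsize))
    cellsize <- if (d[2] > 1) abs(diff(lat[1:2])) else 1
  structure(list(values = values, uncertainty = uncertainty,
                 mask = mask, dates = dates, lat = as.numeric(lat),
                 lon = as.numeric(lon), cellsize = cellsize,
                 varname = varname),
            class = "ecv_stack")
}

#' @export
print.ecv_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ecv_stack '%s'> %d composites x %d x %d grid (%s .. %s), %.1f%% valid\n",
              x$varname, d[1], d[2], d[3], min(x$dates), max(x$dates),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.ecv_stack <- function(x) dim(x$values)

# check two stacks share grid and time base
check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("stacks are not co-registered: dimensions differ")
  if (!isTRUE(all.equal(a$lat, b$lat)) || !isTRUE(all.equal(a$lon, b$lon)))
    stop("stacks are not co-registered: grids differ")
  if (!identical(a$dates, b$dates))
    stop("stacks are not time-aligned")
  invisible(TRUE)
}

#' Region specification
#'
#' A labelled pixel-membership mask selecting the subset of the grid over
#' which regional (per-time-step) metrics are computed, e.g. one land-cover
#' class within one continent.
#'
#' @param member logical matrix (`nrow x ncol` of the grid), `TRUE` for
#'   member pixels; must select at least one pixel.
#' @param label region label.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(member, label = "region") {
  member <- as.matrix(member)
  if (!any(member)) stop("region membership must be non-empty")
  structure(list(member = member, label = label), class = "region_spec")
}
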