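#' Scenario configuration for the synthetic paired-product generator
#'
#' Describes a synthetic pair of LAI/FAPAR products: grid and cadence,
#' land-cover block layout with per-class seasonal leaf-area cycles, the
#' radiative-absorption link `FAPAR = 1 - exp(-k * LAI)`, one of three
#' product uncertainty archetypes, and controlled pathologies (non-coherent
#' increments, an uncertainty trend, a sensor-transition break, quality
#' dropout).
#'
#' The uncertainty archetypes emulate the structure of operational product
#' families:
#' * `"propagated_link"` — a prior-dominated LAI uncertainty budget (large
#'   relative to the value) with an observation-constrained FAPAR posterior
#'   (small relative uncertainty), as in two-stream inversion products;
#' * `"retrieval_spread"` — small relative uncertainties with FAPAR's
#'   relatively larger (ensemble-spread style);
#' * `"decoupled"` — independent uncertainty models per variable
#'   (separate retrieval chains).
#'
#' @param ny,nx grid dimensions (default 16 x 16).
#' @param cellsize cell size in degrees (default 0.01).
#' @param lat0,lon0 grid origin, cell centers at `origin + (i - 0.5) * cellsize`;
#'   defaults place the grid in a Southern-Africa-like window.
#' @param cadence_days composite cadence: 8, 10 or 16 days (default 10).
#' @param years number of years simulated (default 3).
#' @param start_date first composite start date.
#' @param classes land-cover classes laid out as vertical bands across the
#'   grid, each with `baseline` LAI, seasonal `amplitude`, `phase` (day of
#'   year of green-up onset) and `sharpness` (exponent of the clipped
#'   sinusoid).
#' @param k link coefficient of `FAPAR = 1 - exp(-k * LAI)` (default 0.5).
#' @param archetype uncertainty archetype (see above).
#' @param noise_scale multiplier on all uncertainties; 0 gives noise-free
#'   products with zero stated uncertainty (default 1).
#' @param uncertainty_calibration ratio of the actual error standard
#'   deviation to the stated uncertainty (default 1 = perfectly calibrated).
#'   Values below 1 emulate conservative, prior-driven uncertainty budgets
#'   whose stated spread exceeds the realized error.
#' @param p_noncoherent probability that a FAPAR increment's sign is flipped
#'   at a pixel-step (default 0).
#' @param unc_trend_slope fractional growth per year of the *stated*
#'   uncertainty after `break_time` (default 0). This is a calibration
#'   drift: the reported uncertainty entering the confidence level grows
#'   while the realized error does not, emulating products whose
#'   uncertainty magnitudes change over time.
#' @param unc_trend_ecv which variable's uncertainty carries the trend
#'   (`"fapar"`, `"lai"` or `"both"`).
#' @param break_time index of the composite at which the trend/break starts
#'   (default 1 = whole record).
#' @param break_noise_factor multiplier on both the noise and the stated
#'   uncertainty after `break_time` (default 1 = no break), emulating a
#'   sensor transition.
#' @param qc_dropout probability a pixel-composite is flagged invalid.
#' @param seed mandatory integer seed; same seed, same products.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(ny = 16, nx = 16, cellsize = 0.01,
                            lat0 = -25, lon0 = 20,
                            cadence_days = 10, years = 3,
                            start_date = as.Date("2010-01-01"),
                            classes = default_classes(),
                            k = 0.5,
                            archetype = c("propagated_link",
                                          "retrieval_spread", "decoupled"),
                            noise_scale = 1,
                            uncertainty_calibration = 1,
                            p_noncoherent = 0,
                            unc_trend_slope = 0,
                            unc_trend_ecv = c("fapar", "lai", "both"),
                            break_time = 1,
                            break_noise_factor = 1,
                            qc_dropout = 0,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  archetype <- match.arg(archetype)
  unc_trend_ecv <- match.arg(unc_trend_ecv)
  stopifnot(p_noncoherent >= 0, p_noncoherent <= 1, k > 0,
            qc_dropout >= 0, qc_dropout < 1, noise_scale >= 0,
            cadence_days %in% c(8, 10, 16), years > 0,
            break_time >= 1, break_noise_factor > 0,
            uncertainty_calibration >= 0)
  structure(list(ny = ny, nx = nx, cellsize = cellsize, lat0 = lat0,
                 lon0 = lon0, cadence_days = cadence_days, years = years,
                 start_date = as.Date(start_date), classes = classes, k = k,
                 archetype = archetype, noise_scale = noise_scale,
                 uncertainty_calibration = uncertainty_calibration,
                 p_noncoherent = p_noncoherent,
                 unc_trend_slope = unc_trend_slope,
                 unc_trend_ecv = unc_trend_ecv, break_time = break_time,
                 break_noise_factor = break_noise_factor,
                 qc_dropout = qc_dropout, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default land-cover classes of the synthetic scenario
#'
#' Four vegetation structures with seasonal leaf-area parameters typical of
#' a subtropical window: cropland (strong sharp season), forest (high
#' evergreen baseline, mild season), shrub (sparse, weak season) and
#' grassland (low baseline, pronounced season).
#' @return data.frame with columns `class` (code), `name`, `baseline`,
#'   `amplitude`, `phase`, `sharpness`.
#' @export
default_classes <- function() {
  data.frame(
    class = 1:4,
    name = c("cropland", "forest", "shrub", "grassland"),
    baseline = c(0.3, 3.0, 0.2, 0.2),
    amplitude = c(2.5, 1.5, 0.8, 1.5),
    phase = c(300, 280, 320, 310),      # day of year of green-up onset
    sharpness = c(3, 1, 2, 2))
}

# seasonal LAI cycle: clipped, sharpened sinusoid over the day of year
seasonal_lai <- function(doy, baseline, amplitude, phase, sharpness)
  baseline + amplitude * pmax(0, sin(2 * pi * (doy - phase) / 365))^sharpness

# archetype uncertainty models; lai/fapar are true fields
archetype_uncertainty <- function(archetype, lai, fapar, k) {
  switch(archetype,
    # prior-dominated LAI budget, observation-constrained FAPAR posterior:
    # the LAI relative uncertainty is large while FAPAR's stays small.
    # (Exact linear propagation through the link would preserve the
    # signal-to-uncertainty ratio of both variables and erase the
    # asymmetry such products exhibit.)
    propagated_link = list(lai = 0.5 * lai + 0.8,
                           fapar = 0.05 * fapar + 0.02),
    retrieval_spread = list(lai = 0.05 * lai + 0.02,
                            fapar = 0.10 * fapar + 0.02),
    decoupled = list(lai = 0.10 * lai + 0.05,
                     fapar = array(0.05, dim(as.array(fapar)))))
}

#' Generate a synthetic pair of linked LAI/FAPAR products
#'
#' Builds noise-free "true" fields from the per-class seasonal cycles and
#' the exponential light-absorption link, flips FAPAR increment signs with
#' probability `p_noncoherent` (operating on increments so marginal
#' distributions stay realistic), derives the archetype uncertainties
#' (optionally trending and/or breaking at `break_time`), and adds Gaussian
#' noise with standard deviation equal to the stated uncertainty, truncated
#' at the physical bounds (LAI >= 0, FAPAR in \[0, 1\]; the clipping rate is
#' recorded).
#'
#' @param scenario a [scenario_config()].
#' @return list with [ecv_stack()]s `lai` and `fapar`, the land-cover
#'   matrix `lc`, and `truth`: the noise-free fields, the flip mask, the
#'   clipping rates and the scenario itself.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  sc <- scenario
  set.seed(sc$seed)
  nt <- ceiling(sc$years * 365 / sc$cadence_days)
  dates <- sc$start_date + (seq_len(nt) - 1) * sc$cadence_days
  doy <- as.integer(format(dates, "%j"))
  lat <- sc$lat0 + (seq_len(sc$ny) - 0.5) * sc$cellsize
  lon <- sc$lon0 + (seq_len(sc$nx) - 0.5) * sc$cellsize
  # land cover: vertical bands, one per class, recycled across columns
  ncls <- nrow(sc$classes)
  band <- ceiling(seq_len(sc$nx) / (sc$nx / ncls))
  band <- pmin(band, ncls)
  lc <- matrix(sc$classes$class[band], sc$ny, sc$nx, byrow = TRUE)

  shape <- c(nt, sc$ny, sc$nx)
  lai_true <- array(0, shape)
  for (cidx in seq_len(ncls)) {
    cl <- sc$classes[cidx, ]
    cyc <- seasonal_lai(doy, cl$baseline, cl$amplitude, cl$phase, cl$sharpness)
    sel <- which(lc == cl$class, arr.ind = TRUE)
    for (r in seq_len(nrow(sel)))
      lai_true[, sel[r, 1], sel[r, 2]] <- cyc
  }
  fap_link <- 1 - exp(-sc$k * lai_true)

  # non-coherence: flip the sign of FAPAR increments per pixel-step
  flip <- array(FALSE, c(nt - 1, sc$ny, sc$nx))
  fap_true <- fap_link
  if (sc$p_noncoherent > 0) {
    flip <- array(runif((nt - 1) * sc$ny * sc$nx) < sc$p_noncoherent,
                  c(nt - 1, sc$ny, sc$nx))
    for (t in seq_len(nt - 1)) {
      inc <- fap_link[t + 1, , ] - fap_link[t, , ]
      s <- ifelse(flip[t, , ], -1, 1)
      fap_true[t + 1, , ] <- pmin(pmax(fap_true[t, , ] + s * inc, 0), 1)
    }
  }

  unc <- archetype_uncertainty(sc$archetype, lai_true, fap_true, sc$k)
  u_lai <- array(unc$lai, shape) * sc$noise_scale
  u_fap <- array(unc$fapar, shape) * sc$noise_scale
  # sensor break scales noise and stated uncertainty alike; the trend is a
  # calibration drift of the stated uncertainty only
  idx <- seq_len(nt) >= sc$break_time
  bfac <- ifelse(idx, sc$break_noise_factor, 1)
  yrs <- (seq_len(nt) - sc$break_time) * sc$cadence_days / 365
  tfac <- ifelse(idx, 1 + sc$unc_trend_slope * yrs, 1)
  scale_t <- function(u, fac) u * array(rep(fac, prod(shape[2:3])), shape)
  u_lai <- scale_t(u_lai, bfac); u_fap <- scale_t(u_fap, bfac)
  noise_lai <- u_lai; noise_fap <- u_fap
  if (sc$unc_trend_ecv %in% c("lai", "both")) u_lai <- scale_t(u_lai, tfac)
  if (sc$unc_trend_ecv %in% c("fapar", "both")) u_fap <- scale_t(u_fap, tfac)

  n <- prod(shape)
  cal <- sc$uncertainty_calibration
  lai_obs <- lai_true + rnorm(n, sd = cal * noise_lai)
  fap_obs <- fap_true + rnorm(n, sd = cal * noise_fap)
  clip_lai <- mean(lai_obs < 0)
  clip_fap <- mean(fap_obs < 0 | fap_obs > 1)
  lai_obs <- pmax(lai_obs, 0)
  fap_obs <- pmin(pmax(fap_obs, 0), 1)

  mask <- array(runif(n) >= sc$qc_dropout, shape)
  out <- list(
    lai = ecv_stack(lai_obs, u_lai, dates, lat, lon, mask,
                    varname = "lai", cellsize = sc$cellsize),
    fapar = ecv_stack(fap_obs, u_fap, dates, lat, lon, mask,
                      varname = "fapar", cellsize = sc$cellsize),
    lc = lc,
    truth = list(lai_true = lai_true, fapar_true = fap_true, flip = flip,
                 clip_rate_lai = clip_lai, clip_rate_fapar = clip_fap,
                 scenario = sc))
  if (clip_lai + clip_fap > 0)
    message(sprintf("noise clipped at physical bounds: %.2f%% LAI, %.2f%% FAPAR",
                    100 * clip_lai, 100 * clip_fap))
  out
}
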