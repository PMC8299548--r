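test_that("temporal agreement of a noise-free linked pair is perfect", {
  sim <- linked_pair_zero_noise(ny = 4, nx = 4, years = 1)
  ts <- temporal_agreement(sim$lai, sim$fapar)
  expect_true(all(ts$oa == 1))
  expect_true(all(ts$processed_fraction == 1))
})

test_that("summing per-step tables equals one tabulation of all pixel-steps", {
  sim <- generate_scenario(scenario_config(ny = 5, nx = 5, years = 1,
                                           archetype = "retrieval_spread",
                                           qc_dropout = 0.1, seed = 21))
  pc <- paired_changes(sim$lai, sim$fapar)
  ts <- temporal_agreement(pc)
  jc <- ecvagree:::joint_code(ecvagree:::classify_codes(pc, 50))
  all_at_once <- agreement_metrics(ecvagree:::table_from_joint(jc))
  expect_equal(sum(ts$n), all_at_once$n)
  # reconstruct the pooled OA from the per-step diagonal counts
  pooled_oa <- sum(ts$oa * ts$n, na.rm = TRUE) / sum(ts$n)
  expect_equal(pooled_oa, all_at_once$oa, tolerance = 1e-12)
})

test_that("a single-pixel region reproduces the per-pixel map metrics", {
  sim <- generate_scenario(scenario_config(ny = 3, nx = 3, years = 2,
                                           archetype = "decoupled", seed = 22))
  pc <- paired_changes(sim$lai, sim$fapar)
  map <- spatial_agreement(pc)
  member <- matrix(FALSE, 3, 3); member[2, 2] <- TRUE
  ts <- temporal_agreement(pc, region = region_spec(member))
  # pooling the single-pixel series across steps = that pixel's map value
  pooled_oa <- sum(ts$oa * ts$n, na.rm = TRUE) / sum(ts$n)
  expect_equal(pooled_oa, map$oa[2, 2], tolerance = 1e-12)
  expect_equal(sum(ts$n), map$n[2, 2])
})

test_that("injected sign-flip rate reappears as the non-coherent fraction", {
  # in-season record, zero noise: every step of every pixel is significant,
  # so the flipped fraction lands in n13 + n31
  sim <- generate_scenario(scenario_config(
    ny = 10, nx = 10, years = 0.45, start_date = as.Date("2010-11-01"),
    classes = data.frame(class = 1, name = "forest", baseline = 3,
                         amplitude = 1.5, phase = 310, sharpness = 1),
    noise_scale = 0, p_noncoherent = 0.1, seed = 23))
  pc <- paired_changes(sim$lai, sim$fapar)
  jc <- ecvagree:::joint_code(ecvagree:::classify_codes(pc, 50))
  tab <- unclass(ecvagree:::table_from_joint(jc))
  n <- sum(tab)
  phat <- (tab[1, 3] + tab[3, 1]) / n
  expect_gt(n, 1000)
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("empty regions are rejected", {
  expect_error(region_spec(matrix(FALSE, 2, 2)), "non-empty")
})

test_that("monthly climatology averages by composite start month", {
  dates <- seq(as.Date("2010-01-05"), by = 10, length.out = 108)
  oa <- rep(0.8, length(dates))
  winter <- format(dates, "%m") %in% c("12", "01", "02")
  oa[winter] <- 0.4
  series <- data.frame(date = dates, oa = oa)
  clim <- monthly_climatology(series, metrics = "oa")
  expect_equal(clim$mean[clim$month == 1], 0.4)
  expect_equal(clim$mean[clim$month == 7], 0.8)
  expect_equal(which.min(vapply(1:12, function(m) clim$mean[clim$month == m],
                                numeric(1))) %in% c(12, 1, 2), TRUE)
  # a single year reproduces that year with no dispersion across years
  one <- series[1:36, ]
  clim1 <- monthly_climatology(one, metrics = "oa")
  expect_equal(clim1$mean[clim1$month == 1], mean(one$oa[format(one$date, "%m") == "01"]))
  expect_true(all(clim1$n_obs <= 4))
})

test_that("seasonal Mann-Kendall flags monotone series and not constants", {
  dates <- seq(as.Date("2005-01-05"), by = 10, length.out = 180)  # 5 years
  up <- seq_along(dates) * 0.01
  res <- seasonal_mann_kendall(up, dates)
  expect_gt(res$s, 0)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$trend_sign, 1)

  flat <- rep(1, length(dates))
  res0 <- seasonal_mann_kendall(flat, dates)
  expect_equal(res0$s, 0)
  expect_equal(res0$trend_sign, 0)

  expect_error(seasonal_mann_kendall(c(1, 2), seasons = c(1, 2)), "too short")
})

test_that("per-season scores match the Kendall statistic from cor.test", {
  set.seed(31)
  x <- rnorm(48)
  seasons <- rep(1:12, 4)
  res <- seasonal_mann_kendall(x, seasons = seasons)
  s_ref <- sum(vapply(1:12, function(m) {
    xs <- x[seasons == m]
    n <- length(xs)
    # Kendall T counts concordant pairs; S = 2T - n(n-1)/2 for no ties
    tt <- cor.test(seq_len(n), xs, method = "kendall")$statistic
    2 * tt - n * (n - 1) / 2
  }, numeric(1)))
  expect_equal(res$s, s_ref)
})

test_that("seasonal Mann-Kendall holds its size and power", {
  set.seed(32)
  n_years <- 6
  seasons <- rep(1:12, n_years)
  reps <- 400
  # type-I error on white noise
  rej <- vapply(seq_len(reps), function(i) {
    x <- rnorm(length(seasons))
    seasonal_mann_kendall(x, seasons = seasons)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
  # power on a linear trend of two noise-sigmas over the record,
  # superposed on a period-12 seasonal cycle
  sigma <- 1
  trend <- seq(0, 2 * sigma, length.out = length(seasons))
  cycle <- sin(2 * pi * rep(1:12, n_years) / 12)
  hits <- vapply(seq_len(200), function(i) {
    x <- cycle + trend + rnorm(length(seasons), sd = sigma)
    seasonal_mann_kendall(x, seasons = seasons)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("product comparison tests behave on identical, shared and shifted maps", {
  set.seed(33)
  a <- matrix(runif(100, 0.4, 0.9), 10, 10)
  same <- compare_products(a, a)
  expect_equal(same$ks_d, 0)
  expect_equal(same$welch_t, 0)

  shifted <- compare_products(a, a + 0.1)
  expect_lt(shifted$welch_p, 0.001)

  # same distribution: p-values roughly uniform over replicates
  ps <- vapply(1:200, function(i)
    compare_products(matrix(rnorm(50, 0.5, 0.05), 5, 10),
                     matrix(rnorm(50, 0.5, 0.05), 5, 10))$welch_p,
    numeric(1))
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_error(compare_products(1, 2), "at least two")
})

test_that("zonal means recover band values and mark empty bands", {
  v <- matrix(0.5, 6, 4)
  v[1:3, ] <- 0.2                      # southern band
  lat <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  z <- zonal_mean(v, lat = lat, width = 3)
  expect_equal(z$mean[z$lat_lo == -3], 0.2)
  expect_equal(z$mean[z$lat_lo == 0], 0.5)
  # uniform map: every band equals the value
  zu <- zonal_mean(matrix(0.7, 6, 4), lat = lat, width = 1)
  expect_true(all(zu$mean == 0.7))
  # all-invalid band is missing
  v[4:6, ] <- NA
  z2 <- zonal_mean(v, lat = lat, width = 3)
  expect_true(is.na(z2$mean[z2$lat_lo == 0]))
  expect_equal(z2$n_pixels[z2$lat_lo == 0], 0L)
})

test_that("quality masking lowers the processed fraction monotonically", {
  mk <- function(drop) {
    sim <- generate_scenario(scenario_config(ny = 6, nx = 6, years = 1,
                                             qc_dropout = drop, seed = 34))
    mean(temporal_agreement(sim$lai, sim$fapar)$processed_fraction)
  }
  fr <- vapply(c(0, 0.2, 0.5), mk, numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_true(all(fr >= 0 & fr <= 1))
})
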