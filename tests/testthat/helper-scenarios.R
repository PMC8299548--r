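# shared fixtures: tiny stacks and scenarios built in code

# hand-built stack from a time x y x x value array with constant uncertainty
make_stack <- function(values, uncertainty = 0, varname = "ecv",
                       dates = NULL, mask = NULL) {
  values <- as.array(values)
  d <- dim(values)
  if (is.null(dates)) dates <- as.Date("2010-01-01") + (seq_len(d[1]) - 1) * 10
  ecv_stack(values, array(uncertainty, d), dates, mask = mask,
            varname = varname)
}

# deterministic physically linked pair: seasonal LAI, FAPAR through the
# exponential link, both with zero uncertainty
linked_pair_zero_noise <- function(ny = 4, nx = 4, years = 1, seed = 7) {
  generate_scenario(scenario_config(ny = ny, nx = nx, years = years,
                                    noise_scale = 0, seed = seed))
}

# grid-sampled interval overlap/union oracle for the change confidence:
# samples the hull of the two value +/- uncertainty intervals and measures
# the shared fraction; independent of the analytic branch formulas
oracle_confidence <- function(v1, u1, v2, u2, ngrid = 20001) {
  if (v2 == v1) return(0)
  lo <- min(v1 - u1, v2 - u2); hi <- max(v1 + u1, v2 + u2)
  if (hi <= lo) return(0)
  xs <- seq(lo, hi, length.out = ngrid)
  inside <- xs >= max(v1 - u1, v2 - u2) & xs <= min(v1 + u1, v2 + u2)
  100 * (1 - mean(inside))
}

# random change-class factor vectors for property tests
random_classes <- function(n) {
  lv <- c("decrease", "non_significant", "increase")
  factor(sample(lv, n, replace = TRUE), levels = lv)
}
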