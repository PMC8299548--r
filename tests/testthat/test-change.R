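test_that("confidence level reproduces the worked interval cases", {
  # disjoint intervals: full confidence
  r <- confidence_level(0.20, 0.05, 0.50, 0.05)
  expect_equal(r$confidence, 100)
  expect_equal(r$overlap, 0)
  # identical observations: no change, no confidence
  expect_equal(confidence_level(0.30, 0.05, 0.30, 0.05)$confidence, 0)
  # partial overlap: O_l = 0.04 over f_l = 0.20
  r <- confidence_level(0.30, 0.06, 0.38, 0.06)
  expect_equal(r$overlap, 0.04)
  expect_equal(r$full_range, 0.20)
  expect_equal(r$confidence, 80)
  # heavier overlap drops below a 50% threshold
  expect_equal(confidence_level(0.30, 0.10, 0.34, 0.10)$confidence,
               100 / 3, tolerance = 1e-12)
  # zero uncertainties, identical values: f_l = 0 handled as no change
  expect_equal(confidence_level(0.3, 0, 0.3, 0)$confidence, 0)
})

test_that("confidence level rejects negative uncertainties", {
  expect_error(confidence_level(0.3, -0.01, 0.4, 0.05), "non-negative")
})

test_that("confidence level is symmetric, scale invariant and bounded", {
  set.seed(101)
  for (rep in 1:200) {
    v1 <- runif(1, 0, 5); v2 <- runif(1, 0, 5)
    u1 <- runif(1, 0, 1); u2 <- runif(1, 0, 1)
    cf <- confidence_level(v1, u1, v2, u2)$confidence
    expect_gte(cf, 0); expect_lte(cf, 100)
    # direction flips, magnitude identical
    expect_equal(confidence_level(v2, u2, v1, u1)$confidence, cf)
    # multiplying values and uncertainties by c > 0 changes nothing
    cc <- runif(1, 0.1, 10)
    expect_equal(confidence_level(cc * v1, cc * u1, cc * v2, cc * u2)$confidence,
                 cf, tolerance = 1e-9)
  }
})

test_that("growing uncertainties never raise the confidence of a change", {
  set.seed(102)
  for (rep in 1:200) {
    v1 <- runif(1, 0, 5); v2 <- runif(1, 0, 5)
    u1 <- runif(1, 0, 1); u2 <- runif(1, 0, 1)
    grow <- runif(2, 0, 0.5)
    cf0 <- confidence_level(v1, u1, v2, u2)$confidence
    cf1 <- confidence_level(v1, u1 + grow[1], v2, u2 + grow[2])$confidence
    expect_lte(cf1, cf0 + 1e-12)
  }
})

test_that("confidence is 100 exactly when and only when intervals are disjoint", {
  set.seed(103)
  for (rep in 1:200) {
    v1 <- runif(1, 0, 2); v2 <- runif(1, 0, 2)
    u1 <- runif(1, 0, 0.5); u2 <- runif(1, 0, 0.5)
    cf <- confidence_level(v1, u1, v2, u2)$confidence
    disjoint <- (v1 + u1 < v2 - u2) || (v2 + u2 < v1 - u1)
    if (disjoint) expect_equal(cf, 100) else expect_lt(cf, 100)
  }
})

test_that("confidence matches the grid-sampled overlap oracle", {
  # where the branch formulas and the sampled intersection/union coincide:
  # equal uncertainties, and unequal ones with neither interval nested
  set.seed(104)
  for (rep in 1:300) {
    v1 <- runif(1, 0, 5); v2 <- runif(1, 0, 5)
    u <- runif(1, 0.01, 1)
    expect_equal(confidence_level(v1, u, v2, u)$confidence,
                 oracle_confidence(v1, u, v2, u), tolerance = 0.1)
    u1 <- runif(1, 0.01, 1); u2 <- runif(1, 0.01, 1)
    if (abs(v2 - v1) >= abs(u1 - u2))
      expect_equal(confidence_level(v1, u1, v2, u2)$confidence,
                   oracle_confidence(v1, u1, v2, u2), tolerance = 0.1)
  }
})

test_that("classification needs both the right sign and confidence above threshold", {
  expect_equal(as.character(classify_change(0.08, 80)), "increase")
  expect_equal(as.character(classify_change(-0.08, 80)), "decrease")
  expect_equal(as.character(classify_change(0.04, 100 / 3)), "non_significant")
  expect_equal(as.character(classify_change(0, 0)), "non_significant")
  # strict comparison: exactly at the threshold is not significant
  expect_equal(as.character(classify_change(0.1, 50, threshold = 50)),
               "non_significant")
  expect_equal(as.character(classify_change(0.1, 50.001, threshold = 50)),
               "increase")
})

test_that("series classification masks pairwise and checks alignment", {
  n <- 6
  lai <- data.frame(value = rep(2, n), uncertainty = 0.1)
  fap <- data.frame(value = rep(0.6, n), uncertainty = 0.05)
  out <- classify_series(lai, fap)
  expect_equal(nrow(out), n - 1)
  expect_true(all(out$lai_class == "non_significant"))
  expect_true(all(out$fapar_class == "non_significant"))

  # zero uncertainty, strictly monotone link: every step doubly significant
  lai2 <- data.frame(value = seq(0.5, 3, length.out = n), uncertainty = 0)
  fap2 <- data.frame(value = 1 - exp(-0.5 * lai2$value), uncertainty = 0)
  out2 <- classify_series(lai2, fap2)
  expect_true(all(out2$lai_class == "increase"))
  expect_true(all(out2$fapar_class == "increase"))

  # one invalid observation at t = k removes both adjacent steps
  k <- 3
  fap3 <- fap2; fap3$valid <- rep(TRUE, n); fap3$valid[k] <- FALSE
  out3 <- classify_series(lai2, fap3)
  expect_equal(nrow(out3), n - 3)
  expect_false(any(out3$step %in% c(k - 1, k)))

  expect_error(classify_series(lai[1:4, ], fap), "equal length")
  lai$time <- 1:n; fap$time <- c(1:5, 7)
  expect_error(classify_series(lai, fap), "misaligned")
  expect_error(classify_series(lai[1, , drop = FALSE], fap[1, , drop = FALSE]),
               "at least two")
})
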