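#' Confidence level of a temporal change between two uncertain observations
#'
#' Quantifies how confident one can be that a change between two consecutive
#' observations is real, given their one-sigma uncertainty half-widths. Each
#' observation spans the interval `value +/- uncertainty`; the confidence
#' level is the percentage of the full range of the two intervals that is
#' *not* shared between them:
#' \deqn{C_f = 100 (1 - O_l / f_l)}
#' where the overlap length \eqn{O_l} and full range \eqn{f_l} are evaluated
#' branch-wise on the sign of the change. Intervals that do not overlap give
#' 100% confidence; a zero change (or a degenerate zero full range) gives 0%.
#' A negative raw overlap (disjoint intervals) is clamped at zero.
#'
#' @param v1,u1 value and uncertainty of the earlier observation.
#' @param v2,u2 value and uncertainty of the later observation.
#'
#' @return A data.frame with one row per change and columns `delta`
#'   (`v2 - v1`), `overlap` (\eqn{O_l}), `full_range` (\eqn{f_l}) and
#'   `confidence` (\eqn{C_f}, percent in \[0, 100\]). All arguments are
#'   recycled to a common length.
#'
#' @details For an increase (`v2 > v1`) the overlap is
#'   `(v1 + u1) - (v2 - u2)` and the full range `(v2 + u2) - (v1 - u1)`;
#'   the decrease branch mirrors it. Equivalently
#'   \eqn{C_f = 200|\Delta| / (|\Delta| + u_1 + u_2)} clamped at 100, which
#'   makes explicit that growing either uncertainty can only lower the
#'   confidence of a fixed change.
#'
#' @examples
#' confidence_level(0.20, 0.05, 0.50, 0.05)  # disjoint intervals: 100%
#' confidence_level(0.30, 0.06, 0.38, 0.06)  # partial overlap: 80%
#' @export
confidence_level <- function(v1, u1, v2, u2) {
  n <- max(length(v1), length(u1), length(v2), length(u2))
  v1 <- rep_len(as.numeric(v1), n); u1 <- rep_len(as.numeric(u1), n)
  v2 <- rep_len(as.numeric(v2), n); u2 <- rep_len(as.numeric(u2), n)
  if (any(u1 < 0, na.rm = TRUE) || any(u2 < 0, na.rm = TRUE))
    stop("uncertainties must be non-negative")
  delta <- v2 - v1
  # branch on sign of the change; both branches reduce to these envelopes
  up <- delta > 0
  ol <- ifelse(up, (v1 + u1) - (v2 - u2), (v2 + u2) - (v1 - u1))
  fl <- ifelse(up, (v2 + u2) - (v1 - u1), (v1 + u1) - (v2 - u2))
  ol <- pmax(ol, 0)                      # disjoint intervals: full confidence
  cf <- ifelse(delta == 0 | fl <= 0, 0, 100 * (1 - ol / fl))
  cf <- pmin(pmax(cf, 0), 100)
  data.frame(delta = delta, overlap = ol,
             full_range = pmax(fl, 0), confidence = cf)
}

#' Classify a change as increase, decrease or non-significant
#'
#' A change counts as an increase (decrease) only when its confidence level
#' strictly exceeds the threshold and its sign is positive (negative);
#' everything else — including a zero change — is non-significant.
#'
#' @param delta signed change `v2 - v1`.
#' @param confidence confidence level in percent, e.g. from
#'   [confidence_level()].
#' @param threshold confidence threshold in percent (default 50); comparison
#'   is strict (`confidence > threshold`).
#'
#' @return factor with levels `decrease`, `non_significant`, `increase`.
#' @examples
#' classify_change(c(0.08, 0.04, 0), c(80, 33.3, 0))
#' @export
classify_change <- function(delta, confidence, threshold = 50) {
  stopifnot(threshold >= 0, threshold <= 100)
  cls <- ifelse(confidence > threshold & delta > 0, "increase",
         ifelse(confidence > threshold & delta < 0, "decrease",
                "non_significant"))
  cls[is.na(delta) | is.na(confidence)] <- NA
  factor(cls, levels = CHANGE_LEVELS)
}

#' Classify simultaneous changes of two aligned ECV series
#'
#' Walks two time-aligned observation series (e.g. LAI and FAPAR at one
#' pixel), computes the change confidence for every consecutive step of each
#' variable and classifies both. A step is emitted only when both variables
#' are valid at both ends (pairwise-complete masking); no gap filling is
#' performed.
#'
#' @param lai,fapar data.frames with columns `value`, `uncertainty` and
#'   optionally `valid` (logical, default all TRUE) and `time` (used only to
#'   check alignment). Same number of rows, at least 2.
#' @param threshold joint confidence threshold in percent.
#' @param lai_threshold,fapar_threshold optional per-variable thresholds
#'   overriding `threshold`.
#'
#' @return data.frame with one row per emitted step: `step` (index of the
#'   earlier observation), per-variable `delta` and `confidence`
#'   (`lai_delta`, `lai_confidence`, ...), and factors `lai_class`,
#'   `fapar_class`.
#' @export
classify_series <- function(lai, fapar, threshold = 50,
                            lai_threshold = NULL, fapar_threshold = NULL) {
  if (nrow(lai) != nrow(fapar))
    stop("series must be time-aligned with equal length")
  if (!is.null(lai$time) && !is.null(fapar$time) &&
      !isTRUE(all.equal(as.numeric(lai$time), as.numeric(fapar$time))))
    stop("series timestamps are misaligned")
  if (nrow(lai) < 2) stop("need at least two observations")
  lthr <- if (is.null(lai_threshold)) threshold else lai_threshold
  fthr <- if (is.null(fapar_threshold)) threshold else fapar_threshold
  vl <- if (is.null(lai$valid)) rep(TRUE, nrow(lai)) else lai$valid
  vf <- if (is.null(fapar$valid)) rep(TRUE, nrow(fapar)) else fapar$valid
  n <- nrow(lai)
  i <- seq_len(n - 1)
  ok <- vl[i] & vl[i + 1] & vf[i] & vf[i + 1] &
    !is.na(lai$value[i]) & !is.na(lai$value[i + 1]) &
    !is.na(fapar$value[i]) & !is.na(fapar$value[i + 1])
  i <- i[ok]
  cl <- confidence_level(lai$value[i], lai$uncertainty[i],
                         lai$value[i + 1], lai$uncertainty[i + 1])
  cf <- confidence_level(fapar$value[i], fapar$uncertainty[i],
                         fapar$value[i + 1], fapar$uncertainty[i + 1])
  data.frame(step = i,
             lai_delta = cl$delta, lai_confidence = cl$confidence,
             fapar_delta = cf$delta, fapar_confidence = cf$confidence,
             lai_class = classify_change(cl$delta, cl$confidence, lthr),
             fapar_class = classify_change(cf$delta, cf$confidence, fthr))
}
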