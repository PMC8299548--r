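#' Joint confidence-threshold sweep
#'
#' Recomputes the full-period agreement metrics over a region for each
#' confidence threshold, applying the same threshold to both variables.
#' Change confidences are computed once and reclassified per threshold.
#'
#' @param lai,fapar [ecv_stack()] objects, or a [paired_changes()] passed as
#'   `lai`.
#' @param thresholds thresholds in percent (default `c(25, 50, 75)` plus the
#'   endpoints as printed sweeps commonly use; supply your own grid freely).
#' @param region optional [region_spec()].
#' @return data.frame: one row per threshold with the [agreement_metrics()]
#'   columns plus cell counts `n22` (matching non-significant) and
#'   `n_noncoherent` (`n13 + n31`).
#' @export
sweep_joint <- function(lai, fapar = NULL, thresholds = c(25, 50, 75),
                        region = NULL) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 100))
  pc <- if (inherits(lai, "paired_changes")) lai else paired_changes(lai, fapar)
  member <- if (is.null(region)) NULL else region$member
  rows <- lapply(thresholds, function(th) {
    jc <- joint_code(classify_codes(pc, threshold = th))
    if (!is.null(member)) {
      dim(jc) <- c(dim(pc$ok)[1], length(member))
      jc <- jc[, as.vector(member), drop = FALSE]  # time x member-pixel
    }
    tab <- table_from_joint(jc)
    met <- agreement_metrics(tab)
    met$threshold <- th
    met$n22 <- unclass(tab)[2, 2]
    met$n_noncoherent <- unclass(tab)[1, 3] + unclass(tab)[3, 1]
    met
  })
  out <- do.call(rbind, rows)
  out[, c("threshold", setdiff(names(out), "threshold"))]
}

#' Independent per-variable threshold sweep of the non-significant bias
#'
#' Evaluates the non-significant bias (and optionally all metrics) on a grid
#' of LAI-threshold x FAPAR-threshold combinations applied independently to
#' each variable, revealing how the two products' uncertainty magnitudes
#' relate. The default grid covers 0-100% in 1% steps.
#'
#' @inheritParams sweep_joint
#' @param lai_thresholds,fapar_thresholds threshold grids in percent.
#' @return object of class `bns_surface`: list with `bns` matrix (rows = LAI
#'   thresholds, cols = FAPAR thresholds), the two threshold vectors, and
#'   `n` (pairs tabulated, constant across the grid).
#' @export
sweep_independent <- function(lai, fapar = NULL,
                              lai_thresholds = seq(0, 100, by = 1),
                              fapar_thresholds = seq(0, 100, by = 1),
                              region = NULL) {
  stopifnot(all(c(lai_thresholds, fapar_thresholds) >= 0),
            all(c(lai_thresholds, fapar_thresholds) <= 100))
  pc <- if (inherits(lai, "paired_changes")) lai else paired_changes(lai, fapar)
  member <- if (is.null(region)) NULL else region$member
  flat <- function(a) {
    if (is.null(member)) return(a)
    dim(a) <- c(dim(a)[1], length(member))
    a[, as.vector(member), drop = FALSE]
  }
  ld <- flat(pc$lai_delta); lc <- flat(pc$lai_conf)
  fd <- flat(pc$fapar_delta); fc <- flat(pc$fapar_conf)
  ok <- flat(pc$ok)
  ld <- ld[ok]; lc <- lc[ok]; fd <- fd[ok]; fc <- fc[ok]
  n <- length(ld)
  # Bns needs only the four mixed-significance cells, which depend on each
  # variable's significance alone (delta = 0 is never significant). Build
  # per-threshold non-significance indicators and count mixed cells with two
  # crossproducts instead of a double loop over the grid.
  ns_ind <- function(delta, conf, ths)
    vapply(ths, function(th) as.numeric(!(conf > th & delta != 0)),
           numeric(n))                              # n x n_thresholds
  A <- ns_ind(ld, lc, lai_thresholds)               # LAI non-significant
  B <- ns_ind(fd, fc, fapar_thresholds)             # FAPAR non-significant
  n2x <- crossprod(A, 1 - B)                        # n21 + n23
  nx2 <- crossprod(1 - A, B)                        # n12 + n32
  bns <- if (n > 0) (n2x - nx2) / n
         else matrix(NA_real_, length(lai_thresholds), length(fapar_thresholds))
  dimnames(bns) <- list(lai = lai_thresholds, fapar = fapar_thresholds)
  structure(list(bns = bns, lai_thresholds = lai_thresholds,
                 fapar_thresholds = fapar_thresholds, n = n),
            class = "bns_surface")
}

#' @export
print.bns_surface <- function(x, ...) {
  cat(sprintf("<bns_surface> %d x %d thresholds, N = %d, Bns range [%.4f, %.4f]\n",
              nrow(x$bns), ncol(x$bns), x$n, min(x$bns), max(x$bns)))
  invisible(x)
}

#' Zero non-significant-bias locus of a threshold surface
#'
#' Finds the threshold combinations balancing the number of significant
#' cases between the two variables: grid cells where |Bns| falls below one
#' half count (`1/(2N)`, below the resolution of a count ratio) or where Bns
#' changes sign against a grid neighbour. Also reports the joint-threshold
#' crossing along the diagonal.
#'
#' @param surface a [sweep_independent()] result.
#' @param tol zero tolerance on |Bns|; default `1/(2N)`.
#' @return list with `locus` (data.frame `lai_threshold`, `fapar_threshold`,
#'   `bns`), `joint_crossing` (threshold where the diagonal Bns crosses or
#'   reaches zero, `NA` if none) and `diagnostic` message when the locus is
#'   empty.
#' @export
zero_bias_locus <- function(surface, tol = NULL) {
  stopifnot(inherits(surface, "bns_surface"))
  b <- surface$bns
  if (is.null(tol)) tol <- 1 / (2 * max(surface$n, 1))
  near <- abs(b) < tol
  # sign change against right/down neighbours
  sgn <- sign(b)
  flip <- matrix(FALSE, nrow(b), ncol(b))
  if (ncol(b) > 1)
    flip[, -ncol(b)] <- flip[, -ncol(b)] | (sgn[, -ncol(b)] * sgn[, -1] < 0)
  if (nrow(b) > 1)
    flip[-nrow(b), ] <- flip[-nrow(b), ] | (sgn[-nrow(b), ] * sgn[-1, ] < 0)
  hit <- which(near | flip, arr.ind = TRUE)
  locus <- data.frame(
    lai_threshold = surface$lai_thresholds[hit[, 1]],
    fapar_threshold = surface$fapar_thresholds[hit[, 2]],
    bns = b[hit])
  # diagonal (joint threshold) crossing, where the grids share values
  shared <- intersect(surface$lai_thresholds, surface$fapar_thresholds)
  joint <- NA_real_
  if (length(shared) > 1) {
    di <- match(shared, surface$lai_thresholds)
    dj <- match(shared, surface$fapar_thresholds)
    dg <- b[cbind(di, dj)]
    z <- which(abs(dg) < tol | c(sign(dg[-1]) * sign(dg[-length(dg)]) < 0, FALSE))
    if (length(z)) joint <- shared[min(z)]
  }
  diagnostic <- if (nrow(locus) == 0)
    "no zero crossing: Bns keeps one sign over the sweep grid" else NULL
  list(locus = locus, joint_crossing = joint, diagnostic = diagnostic)
}
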