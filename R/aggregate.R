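#' Inverse-variance weighted aggregation of an ECV stack
#'
#' Resamples a stack to a coarser grid by an integer block factor. Each
#' coarse cell value is the uncertainty-weighted average of its valid source
#' pixels,
#' \deqn{R_s = \sum w_i \alpha_i / \sum w_i, \quad w_i = 1/\delta_i^2,}
#' and the propagated cell uncertainty is
#' \deqn{\sigma_s = 1 / \sqrt{\sum w_i},}
#' so adding pixels always tightens the aggregate. Cells whose valid-pixel
#' fraction falls below `min_valid_frac` are marked invalid. Source pixels
#' belong to the coarse cell containing their center (half-open cells
#' anchored at the grid origin), so with exact nesting no pixel is counted
#' twice.
#'
#' @param stack an [ecv_stack()].
#' @param factor integer block size: each coarse cell covers
#'   `factor x factor` source pixels. Grid dimensions must be divisible by
#'   `factor`.
#' @param min_valid_frac minimum fraction of valid source pixels for a
#'   coarse cell to be valid (default 0.5).
#' @param eps uncertainty floor in native units applied to zero
#'   uncertainties before weighting (default 1e-6); flooring events are
#'   reported with a warning.
#' @return an [ecv_stack()] on the coarse grid.
#' @export
aggregate_stack <- function(stack, factor, min_valid_frac = 0.5, eps = 1e-6) {
  stopifnot(inherits(stack, "ecv_stack"), factor >= 1,
            factor == as.integer(factor), eps > 0,
            min_valid_frac >= 0, min_valid_frac <= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(stack)
  d <- dim(stack$values)
  if (d[2] %% factor != 0 || d[3] %% factor != 0)
    stop("grid dimensions must be an integer multiple of the block factor")
  ny <- d[2] %/% factor; nx <- d[3] %/% factor
  u <- stack$uncertainty
  n_floored <- sum(u < eps & stack$mask, na.rm = TRUE)
  if (n_floored > 0)
    warning(sprintf("%d uncertainties below the floor %g were floored",
                    n_floored, eps))
  u <- pmax(u, eps)
  w <- 1 / u^2
  w[!stack$mask] <- 0
  wv <- w * stack$values
  wv[!stack$mask] <- 0
  # block-sum a (time, y, x) array over factor x factor blocks
  block_sum <- function(a) {
    dim(a) <- c(d[1], factor, ny, factor, nx)
    colSums(aperm(a, c(2, 4, 1, 3, 5)), dims = 2)  # sums factor x factor
  }
  sw <- block_sum(w)
  swv <- block_sum(wv)
  nvalid <- block_sum(array(as.numeric(stack$mask), d))
  ok <- nvalid / factor^2 >= min_valid_frac & sw > 0
  vals <- swv / sw
  unc <- 1 / sqrt(sw)
  vals[!ok] <- NA_real_; unc[!ok] <- NA_real_
  agg_coord <- function(cc) colMeans(matrix(cc, nrow = factor))
  ecv_stack(vals, unc, stack$dates,
            lat = agg_coord(stack$lat), lon = agg_coord(stack$lon),
            mask = ok, varname = stack$varname,
            cellsize = stack$cellsize * factor)
}

#' Majority-filter aggregation of a categorical land-cover grid
#'
#' Assigns each coarse cell the modal class of its `factor x factor` source
#' pixels; ties are broken by the smallest class code. Cells with no valid
#' (non-NA) source pixel are `NA`.
#'
#' @param lc integer/factor matrix of class codes.
#' @param factor integer block size; matrix dimensions must be divisible.
#' @return matrix of modal class codes on the coarse grid.
#' @export
landcover_majority <- function(lc, factor) {
  lc <- as.matrix(lc)
  stopifnot(factor >= 1, factor == as.integer(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(lc)
  if (nrow(lc) %% factor != 0 || ncol(lc) %% factor != 0)
    stop("grid dimensions must be an integer multiple of the block factor")
  ny <- nrow(lc) %/% factor; nx <- ncol(lc) %/% factor
  out <- matrix(NA, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    blk <- lc[((i - 1) * factor + 1):(i * factor),
              ((j - 1) * factor + 1):(j * factor)]
    blk <- blk[!is.na(blk)]
    if (length(blk)) {
      cnt <- table(blk)
      best <- names(cnt)[cnt == max(cnt)]
      # ties: smallest class code (numeric codes sort numerically)
      num <- suppressWarnings(as.numeric(best))
      out[i, j] <- if (!anyNA(num)) best[which.min(num)] else sort(best)[1]
    }
  }
  if (is.numeric(lc)) storage.mode(out) <- storage.mode(lc)
  out
}

#' Agreement metrics across spatial resolutions
#'
#' Aggregates both variables to each requested resolution with their own
#' uncertainties ([aggregate_stack()]), resamples the land-cover grid with
#' the majority filter, and re-runs the full-period agreement tabulation per
#' resolution and land-cover class.
#'
#' @param lai,fapar [ecv_stack()] objects on the native grid.
#' @param factors integer aggregation factors (1 = native resolution).
#' @param lc optional land-cover matrix on the native grid; metrics are then
#'   stratified by class (plus an `"all"` stratum).
#' @param threshold confidence threshold in percent.
#' @param min_valid_frac,eps passed to [aggregate_stack()].
#' @return data.frame with one row per factor x stratum: `factor`,
#'   `cellsize`, `stratum`, and the [agreement_metrics()] columns.
#' @export
multiscale_agreement <- function(lai, fapar, factors = c(1, 2, 5, 10),
                                 lc = NULL, threshold = 50,
                                 min_valid_frac = 0.5, eps = 1e-6) {
  check_aligned(lai, fapar)
  rows <- list()
  for (f in factors) {
    la <- aggregate_stack(lai, f, min_valid_frac, eps)
    fa <- aggregate_stack(fapar, f, min_valid_frac, eps)
    pc <- paired_changes(la, fa)
    jc <- joint_code(classify_codes(pc, threshold))
    strata <- list(all = matrix(TRUE, dim(la$values)[2], dim(la$values)[3]))
    if (!is.null(lc)) {
      lcf <- landcover_majority(lc, f)
      for (cls in sort(unique(as.vector(lcf[!is.na(lcf)]))))
        strata[[as.character(cls)]] <- !is.na(lcf) & lcf == cls
    }
    for (s in names(strata)) {
      jcf <- jc
      dim(jcf) <- c(dim(pc$ok)[1], length(strata[[s]]))
      met <- agreement_metrics(
        table_from_joint(jcf[, as.vector(strata[[s]]), drop = FALSE]))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(factor = f, cellsize = la$cellsize, stratum = s), met)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
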