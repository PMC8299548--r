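#' Tabulate simultaneous change-class pairs into a 3x3 contingency table
#'
#' Counts the nine possible combinations of simultaneous change classes.
#' Rows index the first (LAI) variable's class and columns the second
#' (FAPAR) variable's, both ordered decrease, non-significant, increase, so
#' the diagonal holds the physically coherent cases: simultaneous decrease
#' (`n11`), simultaneous non-significance (`n22`) and simultaneous increase
#' (`n33`).
#'
#' @param lai_class,fapar_class factors (or character vectors) of change
#'   classes with levels `decrease`, `non_significant`, `increase`; or a
#'   single data.frame from [classify_series()] passed as `lai_class`.
#'
#' @return A 3x3 integer matrix of class `change_table` with attribute `N`
#'   (total pairs). Pairs with a missing class on either side are dropped.
#' @examples
#' steps <- expand.grid(a = c("decrease", "non_significant", "increase"),
#'                      b = c("decrease", "non_significant", "increase"))
#' change_table(steps$a, steps$b)
#' @export
change_table <- function(lai_class, fapar_class = NULL) {
  if (is.data.frame(lai_class)) {
    fapar_class <- lai_class$fapar_class
    lai_class <- lai_class$lai_class
  }
  a <- factor(lai_class, levels = CHANGE_LEVELS)
  b <- factor(fapar_class, levels = CHANGE_LEVELS)
  keep <- !is.na(a) & !is.na(b)
  tab <- table(lai = a[keep], fapar = b[keep])
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(lai = CHANGE_LEVELS, fapar = CHANGE_LEVELS))
  structure(m, N = sum(m), class = c("change_table", "matrix"))
}

#' @export
print.change_table <- function(x, ...) {
  cat("Simultaneous change contingency table (rows: LAI, cols: FAPAR), N =",
      attr(x, "N"), "\n")
  print(unclass(x)[,])
  invisible(x)
}

# sum a list of change_tables cellwise
sum_change_tables <- function(tables) {
  m <- Reduce(`+`, lapply(tables, unclass))
  structure(m, N = sum(m), class = c("change_table", "matrix"))
}

#' Agreement and bias metrics of a change contingency table
#'
#' Derives the five agreement/bias statistics from a 3x3 simultaneous-change
#' table `n[i, j]` (rows LAI, columns FAPAR; 1 = decrease, 2 =
#' non-significant, 3 = increase):
#' * overall agreement `oa = (n11 + n22 + n33) / N` — fraction of coherent
#'   simultaneous changes;
#' * increase sensitivity `si = 2 n33 / (2 n33 + n32 + n31 + n23 + n13)` and
#'   decrease sensitivity `sd = 2 n11 / (2 n11 + n12 + n13 + n21 + n31)` —
#'   Dice coefficients for the growing and senescence seasons;
#' * non-coherent bias `bnc = (n13 - n31) / N` — imbalance between the two
#'   opposite-sign significant contradictions;
#' * non-significant bias `bns = ((n21 + n23) - (n12 + n32)) / N` — positive
#'   when non-significance is more often on the LAI side.
#'
#' Metrics are returned as fractions; undefined metrics (empty table, or a
#' zero Dice denominator) are `NA`, never 0.
#'
#' @param tab a [change_table()] (any 3x3 count matrix is accepted).
#' @return one-row data.frame with columns `n`, `oa`, `si`, `sd`, `bnc`,
#'   `bns`.
#' @export
agreement_metrics <- function(tab) {
  m <- unclass(tab)
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)), all(m >= 0))
  n <- sum(m)
  den_i <- 2 * m[3, 3] + m[3, 2] + m[3, 1] + m[2, 3] + m[1, 3]
  den_d <- 2 * m[1, 1] + m[1, 2] + m[1, 3] + m[2, 1] + m[3, 1]
  data.frame(
    n   = n,
    oa  = if (n > 0) (m[1, 1] + m[2, 2] + m[3, 3]) / n else NA_real_,
    si  = if (den_i > 0) 2 * m[3, 3] / den_i else NA_real_,
    sd  = if (den_d > 0) 2 * m[1, 1] / den_d else NA_real_,
    bnc = if (n > 0) (m[1, 3] - m[3, 1]) / n else NA_real_,
    bns = if (n > 0) ((m[2, 1] + m[2, 3]) - (m[1, 2] + m[3, 2])) / n
          else NA_real_)
}
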