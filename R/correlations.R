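#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation on pairwise-complete observations with
#' the usual t transform `t = r * sqrt((n-2)/(1-r^2))` against a t
#' distribution with n-2 degrees of freedom.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return A list with `r`, `p` and `n` (complete pairs used). `r` and
#'   `p` are `NA` when either variable has zero variance.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) {
    stop_validation("x and y must have equal length")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop_validation("need >= 3 complete pairs for a correlation, got %d", n)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlation surface between HRV indices and fatigue/load indicators
#'
#' One Pearson cell per (indicator, index) pair, computed on pooled
#' athlete-day rows. Rows whose `quality_flag` is not `"ok"` are
#' excluded when that column is present; missing data are handled
#' pairwise per cell. No multiple-testing correction is applied by
#' default; pass `bh_fdr = TRUE` to append Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param records cohort `data.frame`.
#' @param index_columns character: HRV index columns (e.g.
#'   `"delta_rr_mean"`).
#' @param indicator_columns character: fatigue/workload/training
#'   columns (e.g. `"trimp"`, `"perceived_fatigue"`).
#' @param bh_fdr append a `p_adj` column (Benjamini-Hochberg).
#' @return A long-format `data.frame` (indicator, index, r, p, n).
#' @export
correlation_table <- function(records, index_columns, indicator_columns,
                              bh_fdr = FALSE) {
  unknown <- setdiff(c(index_columns, indicator_columns), names(records))
  if (length(unknown)) {
    stop_validation("unknown column(s): %s", paste(unknown, collapse = ", "))
  }
  if ("quality_flag" %in% names(records)) {
    records <- records[records$quality_flag == "ok", , drop = FALSE]
  }
  grid <- expand.grid(indicator = indicator_columns,
                      index = index_columns,
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    pearson_with_p(records[[grid$indicator[i]]],
                   records[[grid$index[i]]])
  })
  out <- cbind(grid,
               r = vapply(cells, `[[`, numeric(1), "r"),
               p = vapply(cells, `[[`, numeric(1), "p"),
               n = vapply(cells, `[[`, numeric(1), "n"))
  if (bh_fdr) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Williams' test for two dependent correlations sharing one variable
#'
#' Tests whether the correlation of variable 1 with variable 2 equals
#' its correlation with variable 3, given that all three variables are
#' measured on the same n subjects, using the Steiger t2 statistic:
#' \deqn{t = (r_{12}-r_{13})\sqrt{\frac{(n-1)(1+r_{23})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 +
#' 2 r_{12} r_{13} r_{23}} (the determinant of the correlation matrix)
#' and \eqn{\bar r = (r_{12}+r_{13})/2}, referred to a t distribution
#' with n-3 degrees of freedom.
#'
#' @param r12,r13 the two correlations being compared, each in (-1, 1).
#' @param r23 the correlation between the two non-shared variables.
#' @param n number of subjects (>= 4).
#' @return A list with `t_stat`, `df` (= n-3) and two-sided `p`.
#' @examples
#' williams_test(0.5, 0.2, 0.3, 100)
#' @export
williams_test <- function(r12, r13, r23, n) {
  for (nm in c("r12", "r13", "r23")) {
    check_number(get(nm), nm, lower = -1, upper = 1)
    if (abs(get(nm)) >= 1) {
      stop_validation("`%s` must be strictly inside (-1, 1)", nm)
    }
  }
  check_number(n, "n", lower = 4)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) {
    stop_validation(
      "correlations (r12=%.3f, r13=%.3f, r23=%.3f) do not form a valid correlation matrix",
      r12, r13, r23)
  }
  rbar <- (r12 + r13) / 2
  tval <- (r12 - r13) *
    sqrt(((n - 1) * (1 + r23)) /
           (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
  df <- n - 3
  list(t_stat = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}
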