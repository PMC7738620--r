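#' Exhaustive best-subset linear model selection by AIC
#'
#' Fits every subset of the candidate predictors (the empty subset is
#' the intercept-only model, so m candidates yield 2^m fits — 8
#' candidates give the full 256-model sweep) and ranks the fits by
#' ascending [aic_gaussian()] AIC, ties broken by fewer predictors and
#' then lexicographic subset, so the output ordering is deterministic.
#' Rows are deleted listwise per model: each fit uses the rows complete
#' for its own columns. A candidate that is constant across all usable
#' rows is excluded from the enumeration with a warning (it cannot be
#' identified jointly with the intercept). A subset whose design is
#' rank deficient on the available rows (e.g. more athlete-level
#' covariates than distinct athletes) keeps its row in the table with
#' `NA` criteria and sorts last.
#'
#' This is the model-selection procedure behind the orthostatic
#' stress-recovery equations: the response is an orthostatic delta
#' (`delta_rr_mean` or `delta_ln_rmssd`) and the candidates are the
#' eight training/fatigue indicators (km/week, VO2max, HRmax, RPE,
#' perceived fatigue, DOMS, sleep quality, stress).
#'
#' @param formula either a formula `response ~ cand1 + cand2 + ...`
#'   naming the response and candidate predictors, or a character
#'   response column name (then supply `candidates`).
#' @param data cohort `data.frame`; rows with `quality_flag != "ok"`
#'   are dropped when that column is present.
#' @param candidates character vector of candidate predictor columns
#'   (only when `formula` is a column name).
#' @return An object of class `subset_search`: a list with `table`
#'   (one row per fitted subset: predictors, k, aic, r2, adj_r2, n,
#'   rank), `fits` (the `ortho_lm` objects, in table order), `best`
#'   (the AIC-best fit), `response`, `candidates`, `call`.
#' @seealso [fit_ols()], [predict.subset_search()],
#'   [plot.subset_search()]
#' @examples
#' d <- simulate_regression_cohort(n = 200, seed = 1)
#' sel <- best_subset_search(
#'   delta_rr_mean ~ vo2max + training_load + hr_max + rpe +
#'     perceived_fatigue + doms + sleep_quality + stress, d)
#' sel
#' @export
best_subset_search <- function(formula, data, candidates = NULL) {
  cl <- match.call()
  if (inherits(formula, "formula")) {
    response <- deparse(formula[[2L]])
    candidates <- all.vars(formula[[3L]])
  } else {
    response <- formula
    if (is.null(candidates)) {
      stop_validation("supply `candidates` when `formula` is a column name")
    }
  }
  unknown <- setdiff(c(response, candidates), names(data))
  if (length(unknown)) {
    stop_validation("column(s) not in data: %s",
                    paste(unknown, collapse = ", "))
  }
  if ("quality_flag" %in% names(data)) {
    data <- data[data$quality_flag == "ok", , drop = FALSE]
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  const <- candidates[vapply(candidates, function(cn) {
    v <- data[[cn]][!is.na(data[[cn]])]
    length(unique(v)) < 2L
  }, logical(1))]
  if (length(const)) {
    warning(sprintf("excluding constant candidate(s): %s",
                    paste(const, collapse = ", ")), call. = FALSE)
    candidates <- setdiff(candidates, const)
  }
  m <- length(candidates)
  if (m > 16L) stop_validation("more than 16 candidates (2^%d subsets)", m)
  subsets <- lapply(0:(2^m - 1), function(mask) {
    candidates[bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) > 0]
  })
  if (m == 0L) subsets <- list(character())
  fits <- lapply(subsets, function(vars) {
    tryCatch(fit_ols(data[[response]], data[vars],
                     response_name = response),
             error = function(e) {
               structure(list(error = conditionMessage(e)),
                         class = "ortho_lm_failed")
             })
  })
  grab <- function(f, field) {
    if (inherits(f, "ortho_lm_failed")) NA_real_ else f[[field]]
  }
  tab <- data.frame(
    predictors = vapply(subsets, function(v) {
      if (length(v)) paste(v, collapse = "+") else "(intercept only)"
    }, character(1)),
    k = lengths(subsets),
    aic = vapply(fits, grab, numeric(1), "aic"),
    r2 = vapply(fits, grab, numeric(1), "r2"),
    adj_r2 = vapply(fits, grab, numeric(1), "adj_r2"),
    n = vapply(fits, grab, numeric(1), "n"),
    stringsAsFactors = FALSE)
  if (all(is.na(tab$aic))) {
    stop_validation("no candidate subset could be fitted (all designs rank deficient or too few rows)")
  }
  ord <- order(tab$aic, tab$k, tab$predictors, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  fits <- fits[ord]
  subsets <- subsets[ord]
  structure(list(table = tab, fits = fits, subsets = subsets,
                 best = fits[[1L]], response = response,
                 candidates = candidates, call = cl),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, n = 5, ...) {
  cat(sprintf("<subset_search> %s: %d models over %d candidates\n",
              x$response, nrow(x$table), length(x$candidates)))
  cat("Top models by AIC:\n")
  print(utils::head(x$table[c("rank", "predictors", "k", "aic",
                              "adj_r2", "n")], n),
        row.names = FALSE, digits = 5)
  invisible(x)
}

#' Summary of a subset search: top models with coefficients
#'
#' @param object a `subset_search`.
#' @param top number of top-ranked models to detail.
#' @param ... unused.
#' @return A list of class `summary.subset_search` with the ranking
#'   table and per-model coefficient tables (estimate, p-value) for the
#'   `top` models, mirroring the usual published layout.
#' @export
summary.subset_search <- function(object, top = 4, ...) {
  top <- min(top, length(object$fits))
  details <- lapply(object$fits[seq_len(top)], function(f) {
    data.frame(estimate = f$coefficients, p_value = f$p_values)
  })
  structure(list(table = object$table, details = details,
                 response = object$response),
            class = "summary.subset_search")
}

#' @export
print.summary.subset_search <- function(x, ...) {
  cat(sprintf("Best-subset search for %s (%d models)\n",
              x$response, nrow(x$table)))
  for (i in seq_along(x$details)) {
    cat(sprintf("\n-- rank %d: %s (AIC %.1f, adj R2 %.3f) --\n",
                i, x$table$predictors[i], x$table$aic[i],
                x$table$adj_r2[i]))
    print(format(x$details[[i]], digits = 4))
  }
  invisible(x)
}

#' @export
coef.subset_search <- function(object, rank = 1, ...) {
  object$fits[[rank]]$coefficients
}

#' Predict from the AIC-best model of a subset search
#'
#' @param object a `subset_search`.
#' @param newdata covariates passed to [predict.ortho_lm()].
#' @param rank which ranked model to use (default 1, the AIC-best).
#' @param ... unused.
#' @export
predict.subset_search <- function(object, newdata, rank = 1, ...) {
  predict.ortho_lm(object$fits[[rank]], newdata)
}

#' AIC profile of a subset search
#'
#' Plots each fitted subset's AIC against its size, highlighting the
#' AIC-best model — the standard diagnostic for how sharply the
#' criterion separates model sizes.
#'
#' @param x a `subset_search`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subset_search <- function(x, ...) {
  graphics::plot(x$table$k, x$table$aic, xlab = "number of predictors",
                 ylab = "AIC", main = sprintf("Subset search: %s",
                                              x$response), ...)
  graphics::points(x$table$k[1L], x$table$aic[1L], pch = 19, col = 2)
  invisible(x)
}
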