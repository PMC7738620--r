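#' Gaussian AIC from a residual sum of squares
#'
#' The full Gaussian log-likelihood with the error variance profiled
#' out and counted as a parameter:
#' `AIC = n*log(2*pi*rss/n) + n + 2*(p_mean_params + 1)`,
#' where `p_mean_params` counts the mean parameters (intercept
#' included). This is the same convention as `stats::AIC()` on an `lm`
#' fit. Only AIC orderings are used for model ranking, and orderings
#' are invariant to the additive constants that distinguish published
#' AIC conventions.
#'
#' @param rss residual sum of squares (> 0; AIC is undefined for a
#'   perfect fit under this convention).
#' @param n number of observations.
#' @param p_mean_params number of mean parameters, intercept included.
#' @return The AIC value.
#' @examples
#' aic_gaussian(rss = 100, n = 100, p_mean_params = 2)
#' @export
aic_gaussian <- function(rss, n, p_mean_params) {
  check_number(n, "n", lower = 1)
  check_number(p_mean_params, "p_mean_params", lower = 0)
  if (!is.numeric(rss) || length(rss) != 1L || is.na(rss) || rss <= 0) {
    stop_validation("AIC requires rss > 0 (a perfect fit has no finite AIC under this convention)")
  }
  n * log(2 * pi * rss / n) + n + 2 * (p_mean_params + 1)
}

#' Fit an ordinary least-squares linear model
#'
#' Least-squares fit of a response on named predictor columns with an
#' intercept, returning coefficient standard errors from the unbiased
#' residual variance, two-sided t p-values, R-squared, adjusted
#' R-squared and the [aic_gaussian()] information criterion. Rows with
#' any missing value among the response and used predictors are
#' dropped (listwise per model).
#'
#' @param response numeric response vector, or a formula such as
#'   `y ~ x1 + x2` (then `design` is interpreted as a data frame).
#' @param design `data.frame` (or named matrix) of predictor columns;
#'   an intercept is always added. May have zero columns for the
#'   intercept-only model.
#' @param response_name label stored on the fit.
#' @return An object of class `ortho_lm`: coefficients, standard
#'   errors, p-values, `r2`, `adj_r2`, `aic`, `n`, `rss`,
#'   `sigma` (residual SD), plus residuals and fitted values.
#' @examples
#' d <- data.frame(x = 1:20, y = 3 + 2 * (1:20))
#' fit_ols(y ~ x, d)
#' @export
fit_ols <- function(response, design = NULL,
                    response_name = deparse(substitute(response))) {
  if (inherits(response, "formula")) {
    mf <- stats::model.frame(response, data = design, na.action = NULL)
    response_name <- deparse(response[[2L]])
    y <- mf[[1L]]
    design <- mf[-1L]
  } else {
    y <- as.numeric(response)
  }
  if (is.null(design)) design <- data.frame(row.names = seq_along(y))
  design <- as.data.frame(design)
  if (nrow(design) != length(y)) {
    stop_validation("design has %d rows but response has %d values",
                    nrow(design), length(y))
  }
  keep <- if (ncol(design)) stats::complete.cases(y, design) else !is.na(y)
  y <- y[keep]
  X <- cbind(`(Intercept)` = 1, as.matrix(design[keep, , drop = FALSE]))
  n <- length(y)
  p <- ncol(X)
  if (n <= p) {
    stop_validation("n = %d observations cannot identify %d parameters",
                    n, p)
  }
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop_validation("design is rank deficient; collinear column(s): %s",
                    paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  fitted <- drop(X %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- stats::setNames(sqrt(diag(XtXinv) * sigma2), names(coefs))
  tvals <- coefs / se
  pvals <- 2 * stats::pt(-abs(tvals), df = n - p)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0 && n - p > 0) 1 - (1 - r2) * (n - 1) / (n - p)
            else NA_real_
  structure(list(
    response_name = response_name,
    predictor_names = colnames(X)[-1L],
    coefficients = coefs,
    standard_errors = se,
    p_values = pvals,
    r2 = r2, adj_r2 = adj_r2,
    aic = if (rss > 0) aic_gaussian(rss, n, p) else -Inf,
    n = n, rss = rss, sigma = sqrt(sigma2),
    fitted_values = fitted, residuals = res
  ), class = "ortho_lm")
}

#' @export
print.ortho_lm <- function(x, digits = 4, ...) {
  cat(sprintf("<ortho_lm> %s ~ %s\n", x$response_name,
              if (length(x$predictor_names))
                paste(x$predictor_names, collapse = " + ")
              else "1"))
  print(round(x$coefficients, digits))
  cat(sprintf("n = %d, R2 = %.3f, adj. R2 = %.3f, AIC = %.1f\n",
              x$n, x$r2, x$adj_r2, x$aic))
  invisible(x)
}

#' @export
summary.ortho_lm <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients,
                    std_error = object$standard_errors,
                    t_value = object$coefficients / object$standard_errors,
                    p_value = object$p_values)
  structure(list(fit = object, coefficients = tab),
            class = "summary.ortho_lm")
}

#' @export
print.summary.ortho_lm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(format(x$coefficients, digits = 4))
  cat(sprintf("\nResidual SD: %.4g on %d degrees of freedom\n",
              x$fit$sigma, x$fit$n - length(x$fit$coefficients)))
  invisible(x)
}

#' @export
coef.ortho_lm <- function(object, ...) object$coefficients

#' @export
residuals.ortho_lm <- function(object, ...) object$residuals

#' Predict from a fitted or published linear model
#'
#' Evaluates intercept plus the dot product of the model coefficients
#' with the supplied covariates. Extra covariates are ignored with a
#' warning; a missing required covariate is an error naming it.
#'
#' @param object an `ortho_lm` or `published_model`.
#' @param newdata named list, vector or `data.frame` of covariates.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.ortho_lm <- function(object, newdata, ...) {
  predict_linear(object$coefficients, newdata,
                 intercept_name = "(Intercept)")
}

predict_linear <- function(coefs, newdata, intercept_name) {
  if (is.null(newdata)) stop_validation("`newdata` is required")
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  needed <- setdiff(names(coefs), intercept_name)
  missing_cov <- setdiff(needed, names(newdata))
  if (length(missing_cov)) {
    stop_validation("missing covariate(s): %s",
                    paste(missing_cov, collapse = ", "))
  }
  extra <- setdiff(names(newdata), needed)
  if (length(extra)) {
    warning(sprintf("ignoring covariate(s) not in the model: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  pred <- rep(coefs[[intercept_name]], nrow(newdata))
  for (nm in needed) pred <- pred + coefs[[nm]] * newdata[[nm]]
  unname(pred)
}
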