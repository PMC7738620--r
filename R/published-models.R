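#' Packaged predictive equations for the orthostatic RR response
#'
#' Three fixed linear equations relating the orthostatic deltas to
#' training and fatigue indicators, shipped as an immutable JSON
#' fixture:
#' \describe{
#'   \item{`R1_deltaRR`}{delta mean RR (ms) from VO2max, weekly
#'     training volume, HRmax, RPE and the perceived-fatigue item.}
#'   \item{`R1pp_deltaLnRMSSD`}{delta LnRMSSD from the same indicators
#'     plus the stress item.}
#'   \item{`coach_deltaRR`}{a field-friendly delta mean RR equation
#'     using the summed well-being score, HRmax and training volume
#'     only.}
#' }
#'
#' @param model_id one of `"R1_deltaRR"`, `"R1pp_deltaLnRMSSD"`,
#'   `"coach_deltaRR"`; `NULL` lists all ids.
#' @return A `published_model` object (coefficients, response name,
#'   published adjusted R2), or a character vector of ids when
#'   `model_id` is `NULL`.
#' @examples
#' m <- published_model("R1_deltaRR")
#' predict(m, list(vo2max = 53.6, training_load = 187.5,
#'                 hr_max = 185.7, rpe = 5, perceived_fatigue = 4))
#' @export
published_model <- function(model_id = NULL) {
  path <- system.file("extdata", "published_models.json",
                      package = "orthohrv", mustWork = TRUE)
  all <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(model_id)) return(names(all))
  if (!model_id %in% names(all)) {
    stop_validation("unknown model_id %s; available: %s",
                    dQuote(model_id), paste(names(all), collapse = ", "))
  }
  entry <- all[[model_id]]
  structure(list(
    model_id = model_id,
    response_name = entry$response,
    units = entry$units,
    coefficients = unlist(entry$coefficients),
    predictor_names = setdiff(names(entry$coefficients), "(Intercept)"),
    adj_r2 = entry$adj_r2,
    aic_published = entry$aic_published,
    note = entry$note
  ), class = "published_model")
}

#' @export
print.published_model <- function(x, ...) {
  cat(sprintf("<published_model> %s: %s (%s)\n", x$model_id,
              x$response_name, x$units))
  print(x$coefficients)
  cat(sprintf("published adj. R2 = %.3f, AIC = %.1f\n",
              x$adj_r2, x$aic_published))
  invisible(x)
}

#' @export
coef.published_model <- function(object, ...) object$coefficients

#' @rdname predict.ortho_lm
#' @export
predict.published_model <- function(object, newdata, ...) {
  predict_linear(object$coefficients, newdata,
                 intercept_name = "(Intercept)")
}

#' Flag stress-recovery imbalance from measured vs predicted response
#'
#' A measured orthostatic mean-RR delta materially below the value
#' predicted from the athlete's training and fatigue indicators
#' signals that the stress-recovery imbalance is greater than
#' perceived. The rule is `imbalance` iff
#' `measured < predicted - margin`; the default margin of 0 flags any
#' shortfall, and a multiple of the model's residual SD is a natural
#' stricter choice.
#'
#' @param measured_delta_rr measured delta mean RR (ms); vectorised.
#' @param predicted_delta_rr model-predicted delta mean RR (ms).
#' @param margin non-negative tolerance (ms).
#' @return Character vector, `"balanced"` or `"imbalance"` per element.
#' @examples
#' flag_recovery(100, 200)           # "imbalance"
#' flag_recovery(195, 200, margin = 10)  # "balanced"
#' @export
flag_recovery <- function(measured_delta_rr, predicted_delta_rr,
                          margin = 0) {
  check_number(margin, "margin", lower = 0)
  ifelse(measured_delta_rr < predicted_delta_rr - margin,
         "imbalance", "balanced")
}
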