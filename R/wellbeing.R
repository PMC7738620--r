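#' Score the four-item daily well-being questionnaire
#'
#' The daily questionnaire rates perceived general fatigue, sleep
#' quality, delayed-onset muscle soreness (DOMS) and stress, each on a
#' 7-point ordinal scale. The overall well-being score WB is the sum of
#' the four items (range 4-28). Items are stored exactly as entered;
#' no orientation reversal is applied.
#'
#' @param perceived_fatigue,sleep_quality,doms,stress integer ratings
#'   in 1..7 (vectors of equal length are accepted).
#' @return The WB score(s), `perceived_fatigue + sleep_quality + doms +
#'   stress`.
#' @examples
#' wb_score(3, 5, 4, 6)  # 18
#' @export
wb_score <- function(perceived_fatigue, sleep_quality, doms, stress) {
  items <- cbind(perceived_fatigue, sleep_quality, doms, stress)
  if (anyNA(items) || any(items != round(items)) ||
      any(items < 1) || any(items > 7)) {
    stop_validation("well-being items must be integers in 1..7")
  }
  rowSums(items)
}

#' Day-to-day well-being change for one athlete
#'
#' Computes the daily change `delta_wb[t] = wb[t] - wb[t-1]` over
#' consecutive day indices (a gap in the calendar yields a missing
#' delta) and its per-athlete mean over defined deltas. A low average
#' daily change indicates the athlete is only slightly impacted by the
#' stages.
#'
#' @param day_index integer day indices (unique).
#' @param wb WB scores aligned to `day_index`.
#' @return A list with `deltas` (a `data.frame` of `day_index`,
#'   `delta_wb`, one row per day after the first) and `mean_delta_wb`
#'   (`NA` when no delta is defined).
#' @export
delta_wb_series <- function(day_index, wb) {
  if (length(day_index) != length(wb)) {
    stop_validation("day_index and wb must have equal length")
  }
  if (anyDuplicated(day_index)) {
    stop_validation("duplicate day_index in well-being series")
  }
  ord <- order(day_index)
  day_index <- day_index[ord]
  wb <- wb[ord]
  if (length(wb) < 2L) {
    return(list(deltas = data.frame(day_index = integer(),
                                    delta_wb = numeric()),
                mean_delta_wb = NA_real_))
  }
  consecutive <- diff(day_index) == 1L
  d <- ifelse(consecutive, diff(wb), NA_real_)
  deltas <- data.frame(day_index = day_index[-1L], delta_wb = d)
  list(deltas = deltas,
       mean_delta_wb = if (all(is.na(d))) NA_real_
                       else mean(d, na.rm = TRUE))
}

#' Mean well-being change versus pre-event training load
#'
#' Summarises each athlete's mean daily well-being change against the
#' pre-event weekly training volume, plus one aggregate row per
#' distinct training load (the mean over athletes sharing that load) —
#' the table behind the training-level adaptation plot.
#'
#' @param records cohort `data.frame` with columns `athlete_id`,
#'   `day_index`, `wb`.
#' @param profiles `data.frame` with columns `athlete_id`,
#'   `training_load` (km/week).
#' @return A list with `athletes` (athlete_id, training_load,
#'   mean_delta_wb) and `groups` (training_load, mean_delta_wb, n).
#' @export
wb_vs_training <- function(records, profiles) {
  need <- setdiff(c("athlete_id", "day_index", "wb"), names(records))
  if (length(need)) {
    stop_validation("records lack column(s): %s",
                    paste(need, collapse = ", "))
  }
  ids <- unique(records$athlete_id)
  missing_prof <- setdiff(ids, profiles$athlete_id)
  if (length(missing_prof)) {
    stop_validation("no profile for athlete(s): %s",
                    paste(missing_prof, collapse = ", "))
  }
  per <- lapply(ids, function(id) {
    sub <- records[records$athlete_id == id, ]
    data.frame(
      athlete_id = id,
      training_load =
        profiles$training_load[match(id, profiles$athlete_id)],
      mean_delta_wb =
        delta_wb_series(sub$day_index, sub$wb)$mean_delta_wb)
  })
  athletes <- do.call(rbind, per)
  groups <- do.call(rbind, lapply(
    split(athletes, athletes$training_load), function(g) {
      data.frame(training_load = g$training_load[1L],
                 mean_delta_wb = mean(g$mean_delta_wb),
                 n = nrow(g))
    }))
  rownames(groups) <- NULL
  list(athletes = athletes, groups = groups)
}
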