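#' Time in the five heart-rate zones
#'
#' Partitions a continuous HR trace into the five training zones at
#' 50-60, 60-70, 70-80, 80-90 and 90-100% of the athlete's maximal
#' heart rate. Each zone is left-closed (a sample at exactly 70% falls
#' in zone 3); samples above 100% HRmax clip into zone 5; time below
#' 50% accrues to no zone. Duration is attributed sample-and-hold:
#' each sample owns the interval to the next timestamp, and the final
#' sample owns the median sampling interval.
#'
#' @param time_s numeric vector of sample times (s), strictly increasing.
#' @param hr_bpm numeric vector of heart rates (bpm), positive.
#' @param hr_max the athlete's maximal heart rate (bpm).
#' @return Numeric vector of length 5: minutes spent in zones 1-5.
#' @examples
#' hr_zone_durations(0:599, rep(102, 600), hr_max = 185.7)
#' @export
hr_zone_durations <- function(time_s, hr_bpm, hr_max) {
  check_number(hr_max, "hr_max", lower = 1)
  if (length(time_s) != length(hr_bpm) || !length(time_s)) {
    stop_validation("time_s and hr_bpm must be non-empty, equal length")
  }
  if (any(diff(time_s) <= 0)) {
    stop_validation("HR trace timestamps must be strictly increasing")
  }
  if (any(hr_bpm <= 0)) stop_validation("heart rates must be positive")
  dt <- diff(time_s)
  dt <- c(dt, if (length(dt)) stats::median(dt) else 1)
  zone <- findInterval(hr_bpm / hr_max, c(0.5, 0.6, 0.7, 0.8, 0.9))
  zone <- pmin(zone, 5L)
  vapply(1:5, function(k) sum(dt[zone == k]) / 60, numeric(1))
}

#' Edwards training impulse (TRIMP)
#'
#' The Edwards score weights the minutes accumulated in each of the
#' five HR zones by the zone index: TRIMP = 1*z1 + 2*z2 + 3*z3 + 4*z4
#' + 5*z5.
#'
#' @param zone_minutes numeric vector of length 5, minutes per zone.
#' @return The TRIMP score (points).
#' @examples
#' edwards_trimp(c(10, 10, 10, 10, 10))  # 150
#' @export
edwards_trimp <- function(zone_minutes) {
  if (length(zone_minutes) != 5L || anyNA(zone_minutes)) {
    stop_validation("zone_minutes must be 5 non-missing durations")
  }
  if (any(zone_minutes < 0)) {
    stop_validation("zone durations must be non-negative")
  }
  sum(zone_minutes * 1:5)
}

#' Stage workload from an HR trace
#'
#' @inheritParams hr_zone_durations
#' @param rpe Borg CR-10 rating of perceived exertion (0-10, may be NA).
#' @param stage_km stage distance (km).
#' @return A one-row `data.frame` with zone minutes, `trimp`, `rpe`
#'   and `stage_km`.
#' @export
stage_workload <- function(time_s, hr_bpm, hr_max, rpe = NA_real_,
                           stage_km = NA_real_) {
  check_number(rpe, "rpe", lower = 0, upper = 10, allow_na = TRUE)
  zm <- hr_zone_durations(time_s, hr_bpm, hr_max)
  out <- as.data.frame(as.list(stats::setNames(zm, paste0("zone", 1:5))))
  out$trimp <- edwards_trimp(zm)
  out$rpe <- rpe
  out$stage_km <- stage_km
  out
}
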