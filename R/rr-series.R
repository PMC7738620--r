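#' Construct an RR-interval series
#'
#' An `rr_series` is an ordered sequence of beat-to-beat intervals in
#' milliseconds, the raw measurement unit of the pipeline. Cumulative
#' beat time (seconds) is derived on demand.
#'
#' @param intervals numeric vector of beat-to-beat intervals (ms), all
#'   strictly positive.
#' @return An object of class `rr_series` (a numeric vector).
#' @examples
#' rr_series(c(800, 810, 790))
#' @export
rr_series <- function(intervals = numeric()) {
  x <- as.numeric(intervals)
  if (anyNA(x)) stop_validation("RR intervals must not contain NA")
  if (length(x) && any(x <= 0)) {
    stop_validation("RR intervals must be strictly positive (found %s ms)",
                    format(min(x)))
  }
  structure(x, class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.1f s", length(x),
              sum(unclass(x)) / 1000))
  if (length(x)) cat(sprintf(", mean RR %.1f ms", mean(unclass(x))))
  cat("\n")
  invisible(x)
}

#' Cumulative beat times of an RR series
#'
#' @param series an [rr_series()].
#' @return Numeric vector of cumulative time (s) at the end of each beat.
#' @export
rr_times <- function(series) cumsum(as.numeric(series)) / 1000

#' Read an RR series from a plain-text export
#'
#' Reads the common heart-rate-monitor export format: one RR interval in
#' milliseconds per line. Blank lines and surrounding whitespace are
#' tolerated. An empty file yields a valid zero-length series.
#'
#' @param path file path.
#' @return An [rr_series()].
#' @export
read_rr_text <- function(path) {
  if (!file.exists(path)) stop_validation("RR file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  tok <- trimws(lines)
  keep <- nzchar(tok)
  vals <- suppressWarnings(as.numeric(tok[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop_validation("non-numeric RR value %s at line %d of %s",
                    dQuote(tok[bad]), bad, path)
  }
  if (length(vals) && any(vals <= 0)) {
    bad <- which(keep)[which(vals <= 0)[1L]]
    stop_validation("non-positive RR interval at line %d of %s", bad, path)
  }
  rr_series(vals)
}

#' Write an RR series as plain text
#'
#' @param series an [rr_series()].
#' @param path output file path; one interval (ms) per line.
#' @return `path`, invisibly.
#' @export
write_rr_text <- function(series, path) {
  writeLines(format(as.numeric(series), scientific = FALSE, trim = TRUE),
             path)
  invisible(path)
}

#' Correct ectopic-beat artifacts by local-median screening
#'
#' Flags a beat when it deviates from the median of its 11 nearest
#' accepted neighbours by more than `threshold_ms`, then replaces all
#' flagged beats by piecewise-cubic interpolation over the accepted
#' beats. The beat count is preserved (beats are corrected, not
#' removed). The default 450 ms threshold is a "very low" correction
#' level appropriate for resting recordings; supraventricular ectopy in
#' slow rhythms deviates by less, so a tighter threshold (150-250 ms)
#' should be passed when premature beats must be caught.
#'
#' @param series an [rr_series()] of at least 12 beats.
#' @param threshold_ms deviation threshold (ms) above which a beat is
#'   flagged as an artifact.
#' @return A list with `series` (corrected [rr_series()]),
#'   `corrected_fraction` (flagged beats / total), and `flagged`
#'   (logical vector).
#' @export
correct_artifacts <- function(series, threshold_ms = 450) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 12L) {
    stop_validation("artifact correction needs >= 12 beats, got %d", n)
  }
  check_number(threshold_ms, "threshold_ms", lower = 0)
  ## fast path: no beat can deviate from any neighbour median by more
  ## than the full range of the series
  if (diff(range(x)) <= threshold_ms) {
    return(list(series = rr_series(x), corrected_fraction = 0,
                flagged = logical(n)))
  }
  accepted <- rep(TRUE, n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    idx <- which(accepted)
    idx <- idx[idx != i]
    nb <- idx[order(abs(idx - i))][seq_len(min(11L, length(idx)))]
    if (abs(x[i] - stats::median(x[nb])) > threshold_ms) {
      flagged[i] <- TRUE
      accepted[i] <- FALSE
    }
  }
  if (any(flagged)) {
    good <- which(!flagged)
    x[flagged] <- stats::spline(good, x[good], xout = which(flagged),
                                method = "fmm")$y
    x[flagged] <- pmax(x[flagged], 1)  # interpolation must stay positive
  }
  list(series = rr_series(x),
       corrected_fraction = sum(flagged) / n,
       flagged = flagged)
}

#' Extract the trailing analysis window of an RR series
#'
#' Returns the minimal suffix of beats whose cumulative duration spans
#' at least `window_s` seconds — the standard "last 5 minutes of each
#' position" convention for short-term orthostatic recordings. Interval
#' values are preserved exactly (no resampling).
#'
#' @param series an [rr_series()].
#' @param window_s window duration in seconds (default 300).
#' @param phase optional label used in error messages (e.g. "supine").
#' @return An [rr_series()] spanning `>= window_s` seconds.
#' @export
extract_window <- function(series, window_s = 300, phase = NULL) {
  x <- as.numeric(series)
  check_number(window_s, "window_s", lower = 0)
  total_ms <- sum(x)
  if (total_ms < window_s * 1000) {
    lab <- if (is.null(phase)) "recording" else sprintf("%s phase", phase)
    stop_validation("%s spans %.1f s, shorter than the %.0f-s window",
                    lab, total_ms / 1000, window_s)
  }
  rev_cum <- rev(cumsum(rev(x)))
  start <- max(which(rev_cum >= window_s * 1000))
  rr_series(x[start:length(x)])
}

#' Assemble a quality-controlled orthostatic session
#'
#' Applies artifact correction and trailing-window extraction to the
#' supine and standing recordings of one athlete-day, and applies the
#' 5% quality rule: a session in which either phase needed 5% or more
#' of its beats corrected is flagged `rejected` (it is retained, not
#' dropped, so cohort tables stay rectangular; downstream statistics
#' skip flagged rows).
#'
#' @param supine,standing [rr_series()] recordings (nominally 7 min each).
#' @param athlete_id,day_index identifiers carried into the session.
#' @param threshold_ms artifact threshold passed to [correct_artifacts()].
#' @param window_s analysis window passed to [extract_window()].
#' @param reject_at corrected-beat fraction at or above which the
#'   session is rejected (default 0.05).
#' @return An object of class `orthostatic_session`: a list with the two
#'   windowed [rr_series()], corrected fractions per phase, and
#'   `quality_flag` (`"ok"` or `"rejected"`).
#' @export
assemble_session <- function(supine, standing, athlete_id = NA,
                             day_index = NA, threshold_ms = 450,
                             window_s = 300, reject_at = 0.05) {
  phases <- list(supine = supine, standing = standing)
  out <- list(athlete_id = athlete_id, day_index = day_index)
  for (ph in names(phases)) {
    x <- rr_series(as.numeric(phases[[ph]]))
    if (!length(x)) stop_validation("%s phase is empty", ph)
    corr <- tryCatch(correct_artifacts(x, threshold_ms),
                     error = function(e) {
                       stop_validation("%s phase: %s", ph, conditionMessage(e))
                     })
    win <- extract_window(corr$series, window_s, phase = ph)
    out[[ph]] <- win
    out[[paste0("corrected_fraction_", ph)]] <- corr$corrected_fraction
  }
  frac <- c(out$corrected_fraction_supine, out$corrected_fraction_standing)
  out$quality_flag <- if (any(frac >= reject_at)) "rejected" else "ok"
  structure(out, class = "orthostatic_session")
}

#' @export
print.orthostatic_session <- function(x, ...) {
  cat(sprintf(
    "<orthostatic_session> athlete %s day %s [%s]\n",
    format(x$athlete_id), format(x$day_index), x$quality_flag))
  cat(sprintf("  supine:   %d beats, %.2f%% corrected\n",
              length(x$supine), 100 * x$corrected_fraction_supine))
  cat(sprintf("  standing: %d beats, %.2f%% corrected\n",
              length(x$standing), 100 * x$corrected_fraction_standing))
  invisible(x)
}
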