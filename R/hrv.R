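#' Time-domain HRV indices of an RR series
#'
#' Computes the mean RR interval, mean heart rate, RMSSD (root mean
#' square of successive RR differences — the standard short-term index
#' of cardiac parasympathetic modulation) and its natural logarithm.
#' `ln_rmssd` is reported as `NA` when RMSSD is exactly zero (a
#' zero-variability series), never as `-Inf`, so cohort tables stay
#' numeric.
#'
#' @param series an [rr_series()] with at least 2 beats.
#' @return A list with `mean_rr` (ms), `mean_hr` (bpm = 60000/mean_rr),
#'   `rmssd` (ms) and `ln_rmssd` (ln ms).
#' @examples
#' time_domain_indices(rr_series(c(800, 810, 790, 805)))
#' @export
time_domain_indices <- function(series) {
  x <- as.numeric(series)
  if (length(x) < 1L) stop_validation("need at least 1 beat for mean RR")
  if (length(x) < 2L) {
    stop_validation("RMSSD is undefined for a single-beat series")
  }
  d <- diff(x)
  rmssd <- sqrt(mean(d^2))
  list(mean_rr = mean(x),
       mean_hr = 60000 / mean(x),
       rmssd = rmssd,
       ln_rmssd = if (rmssd > 0) log(rmssd) else NA_real_)
}

#' Frequency-domain HRV indices by Welch's periodogram
#'
#' The irregularly sampled RR tachogram is interpolated onto a uniform
#' grid (cubic spline against cumulative beat time), linearly
#' detrended, and its power spectral density estimated by Welch's
#' method: Hann-tapered segments of `segment_s` seconds at
#' `overlap_fraction` overlap, periodograms averaged, one-sided
#' normalisation such that a pure sinusoid of amplitude A integrates to
#' A^2/2 (ms^2) in its band. Band powers are integrated over
#' LF = [0.04, 0.15) Hz and HF = [0.15, 0.40] Hz (half-open junction so
#' no bin is double-counted). Normalized units follow
#' HFnu = HF/(LF+HF), LFnu = LF/(LF+HF): power below 0.04 Hz (VLF) is
#' excluded from the denominator.
#'
#' @param series an [rr_series()] spanning at least `segment_s` seconds.
#' @param resample_hz uniform resampling rate (Hz), default 4.
#' @param segment_s Welch segment length (s), default 150.
#' @param overlap_fraction segment overlap in (0, 1), default 0.5.
#' @return A list with `lf_abs`, `hf_abs` (ms^2), `lf_nu`, `hf_nu`
#'   (fractions; `NA` when total band power is numerically zero) and
#'   `lf_hf_ratio`.
#' @export
spectral_powers <- function(series, resample_hz = 4, segment_s = 150,
                            overlap_fraction = 0.5) {
  x <- as.numeric(series)
  check_number(resample_hz, "resample_hz", lower = 1)
  check_number(segment_s, "segment_s", lower = 1)
  check_number(overlap_fraction, "overlap_fraction", lower = 0, upper = 0.95)
  tt <- cumsum(x) / 1000
  span <- tt[length(tt)] - tt[1L]
  if (length(x) < 4L || span < segment_s) {
    stop_validation(
      "recording spans %.1f s, shorter than one %.0f-s Welch segment",
      if (length(x)) span else 0, segment_s)
  }
  grid <- seq(tt[1L], tt[length(tt)], by = 1 / resample_hz)
  xi <- stats::spline(tt, x, xout = grid, method = "fmm")$y
  xi <- stats::lsfit(grid, xi)$residuals     # linear detrend

  nseg <- as.integer(round(segment_s * resample_hz))
  step <- max(1L, as.integer(round(nseg * (1 - overlap_fraction))))
  starts <- seq(1L, length(xi) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  scale <- resample_hz * sum(w^2)
  nf <- nseg %/% 2L
  psd <- numeric(nf)
  for (s in starts) {
    seg <- xi[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2 / scale
    half <- sp[2:(nf + 1L)] * 2          # one-sided, DC dropped
    psd <- psd + half
  }
  psd <- psd / length(starts)
  freq <- (1:nf) * resample_hz / nseg
  df <- resample_hz / nseg
  lf <- sum(psd[freq >= 0.04 & freq < 0.15]) * df
  hf <- sum(psd[freq >= 0.15 & freq <= 0.40]) * df
  tot <- lf + hf
  list(lf_abs = lf, hf_abs = hf,
       lf_nu = if (tot > 1e-10) lf / tot else NA_real_,
       hf_nu = if (tot > 1e-10) hf / tot else NA_real_,
       lf_hf_ratio = if (hf > 1e-10) lf / hf else NA_real_)
}

#' All HRV indices for one recording phase
#'
#' Convenience wrapper combining [time_domain_indices()] and
#' [spectral_powers()].
#'
#' @inheritParams spectral_powers
#' @return A list of class `phase_indices` with the union of both index
#'   sets.
#' @export
phase_indices <- function(series, resample_hz = 4, segment_s = 150,
                          overlap_fraction = 0.5) {
  out <- c(time_domain_indices(series),
           spectral_powers(series, resample_hz, segment_s,
                           overlap_fraction))
  structure(out, class = "phase_indices")
}

#' Orthostatic delta statistics of one session
#'
#' The orthostatic deltas are supine minus standing values of the
#' corresponding phase index. The mean-RR delta is the primary
#' stress-recovery indicator: standing normally shortens RR via vagal
#' withdrawal, so a healthy response gives a large positive delta and a
#' blunted (fatigued) response a small one.
#'
#' @param supine,standing phase index lists as returned by
#'   [time_domain_indices()] or [phase_indices()].
#' @return A list with `delta_rr_mean` (ms), `delta_rmssd` (ms) and
#'   `delta_ln_rmssd` (`NA` when either phase's LnRMSSD is undefined).
#' @export
orthostatic_deltas <- function(supine, standing) {
  for (f in c("mean_rr", "rmssd")) {
    if (is.null(supine[[f]]) || is.null(standing[[f]])) {
      stop_validation("phase indices lack field `%s`", f)
    }
  }
  ln_sup <- supine$ln_rmssd
  ln_sta <- standing$ln_rmssd
  list(delta_rr_mean = supine$mean_rr - standing$mean_rr,
       delta_rmssd = supine$rmssd - standing$rmssd,
       delta_ln_rmssd = if (is.null(ln_sup) || is.null(ln_sta) ||
                            is.na(ln_sup) || is.na(ln_sta)) NA_real_
                        else ln_sup - ln_sta)
}

#' HRV indices and deltas for a whole session
#'
#' Computes [phase_indices()] for both phases of an
#' [assemble_session()] result and the [orthostatic_deltas()] between
#' them, as one flat row suitable for binding into a cohort table.
#'
#' @param session an `orthostatic_session`.
#' @param spectral compute frequency-domain indices (default TRUE;
#'   time-domain only when FALSE, which is considerably faster).
#' @param ... passed to [spectral_powers()].
#' @return A one-row `data.frame` with per-phase indices (suffixes
#'   `_sup`, `_sta`), the three deltas, corrected fractions and the
#'   quality flag.
#' @export
session_hrv <- function(session, spectral = TRUE, ...) {
  idx <- lapply(list(sup = session$supine, sta = session$standing),
                function(s) {
                  if (spectral) phase_indices(s, ...)
                  else time_domain_indices(s)
                })
  deltas <- orthostatic_deltas(idx$sup, idx$sta)
  row <- c(list(athlete_id = session$athlete_id,
                day_index = session$day_index),
           stats::setNames(idx$sup, paste0(names(idx$sup), "_sup")),
           stats::setNames(idx$sta, paste0(names(idx$sta), "_sta")),
           deltas,
           list(corrected_fraction_supine = session$corrected_fraction_supine,
                corrected_fraction_standing = session$corrected_fraction_standing,
                quality_flag = session$quality_flag))
  as.data.frame(row, stringsAsFactors = FALSE)
}
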