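#' Synthesise an RR tachogram with controlled mean and RMSSD
#'
#' Builds a beat series as a constant mean plus two fixed-frequency
#' sinusoids — one in the HF band (respiratory modulation) and one in
#' the LF band — plus white noise. Fixed sinusoids rather than an
#' autoregressive process make the band powers analytically checkable.
#' Amplitudes are solved from the RMSSD target: a sinusoid of
#' amplitude A at frequency f sampled at beat interval delta
#' contributes `2 A^2 sin^2(pi f delta)` to the squared RMSSD, white
#' noise of SD sigma contributes `2 sigma^2`. After generation the
#' deviations are rescaled so the realized RMSSD equals the target
#' exactly and the realized mean RR equals the target exactly.
#'
#' @param mean_rr target mean RR (ms), in (300, 2000).
#' @param rmssd_target target RMSSD (ms, >= 0; 0 yields a constant
#'   series).
#' @param duration_s cumulative duration to span (s).
#' @param resp_freq,lf_freq modulation frequencies (Hz).
#' @param hf_share,lf_share fraction of squared RMSSD carried by each
#'   sinusoid (remainder: white noise).
#' @param seed integer seed.
#' @return An [rr_series()] spanning at least `duration_s` seconds.
#' @export
simulate_rr_tachogram <- function(mean_rr, rmssd_target,
                                  duration_s = 420,
                                  resp_freq = 0.25, lf_freq = 0.10,
                                  hf_share = 0.65, lf_share = 0.25,
                                  seed = 1) {
  check_number(mean_rr, "mean_rr", lower = 300, upper = 2000)
  check_number(rmssd_target, "rmssd_target", lower = 0)
  check_number(duration_s, "duration_s", lower = 1)
  if (hf_share < 0 || lf_share < 0 || hf_share + lf_share > 1) {
    stop_validation("hf_share and lf_share must be >= 0 and sum to <= 1")
  }
  delta <- mean_rr / 1000
  amp <- function(share, f) {
    if (share == 0 || rmssd_target == 0) return(0)
    sqrt(share * rmssd_target^2 / (2 * sin(pi * f * delta)^2))
  }
  a_hf <- amp(hf_share, resp_freq)
  a_lf <- amp(lf_share, lf_freq)
  noise_share <- 1 - hf_share - lf_share
  sigma <- if (rmssd_target == 0) 0 else
    sqrt(noise_share * rmssd_target^2 / 2)
  if (a_hf + a_lf + 4 * sigma >= mean_rr) {
    stop_validation(
      "RMSSD target %.1f ms is infeasible at mean RR %.0f ms (modulation would force RR <= 0)",
      rmssd_target, mean_rr)
  }
  set.seed(seed)
  n_max <- ceiling(duration_s * 1000 / mean_rr) + 50L
  eps <- stats::rnorm(n_max, 0, sigma)
  rr <- numeric(n_max)
  tt <- 0
  n <- 0L
  while (tt < duration_s) {
    n <- n + 1L
    rr[n] <- mean_rr + a_hf * sin(2 * pi * resp_freq * tt) +
      a_lf * sin(2 * pi * lf_freq * tt) + eps[n]
    tt <- tt + rr[n] / 1000
  }
  rr <- rr[seq_len(n)]
  dev <- rr - mean(rr)
  if (rmssd_target > 0) {
    realized <- sqrt(mean(diff(rr)^2))
    if (realized > 0) dev <- dev * (rmssd_target / realized)
  } else {
    dev <- dev * 0
  }
  out <- mean_rr + dev
  if (any(out <= 0)) {
    stop_validation("RMSSD target %.1f ms forces non-positive RR at mean %.0f ms",
                    rmssd_target, mean_rr)
  }
  rr_series(out)
}

#' Simulate a paired supine/standing orthostatic RR recording
#'
#' One synthetic orthostatic test: a supine and a standing tachogram
#' (each spanning at least 7 minutes by default) built by
#' [simulate_rr_tachogram()] at the requested per-phase mean RR and
#' RMSSD targets. The realized mean RR of each phase equals its target
#' exactly, so the downstream mean-RR delta of the clean recording
#' equals `mean_rr_supine - mean_rr_standing` up to windowing effects.
#'
#' @param mean_rr_supine,mean_rr_standing target mean RR per phase
#'   (ms), in (300, 2000).
#' @param rmssd_supine,rmssd_standing target RMSSD per phase (ms).
#' @param duration_s per-phase duration (s), default 420 (7 min).
#' @param resp_freq,lf_freq,hf_share,lf_share see
#'   [simulate_rr_tachogram()].
#' @param seed integer seed (the standing phase uses a derived
#'   substream).
#' @return A list with `supine` and `standing` [rr_series()].
#' @export
simulate_orthostatic_rr <- function(mean_rr_supine, mean_rr_standing,
                                    rmssd_supine = 50,
                                    rmssd_standing = 25,
                                    duration_s = 420,
                                    resp_freq = 0.25, lf_freq = 0.10,
                                    hf_share = 0.65, lf_share = 0.25,
                                    seed = 1) {
  list(
    supine = simulate_rr_tachogram(
      mean_rr_supine, rmssd_supine, duration_s, resp_freq, lf_freq,
      hf_share, lf_share, seed = substream_seed(seed, "supine")),
    standing = simulate_rr_tachogram(
      mean_rr_standing, rmssd_standing, duration_s, resp_freq, lf_freq,
      hf_share, lf_share, seed = substream_seed(seed, "standing")))
}

#' Inject premature-beat artifact pairs into an RR series
#'
#' Corrupts a clean series with synthetic supraventricular ectopy for
#' quality-control testing: each corrupted pair has its first interval
#' shortened to 60% of the local mean and the following interval
#' lengthened by the amount removed, so cumulative recording time is
#' unchanged. `floor(fraction * n / 2)` pairs — `2*floor(fraction*n/2)`
#' beats — are corrupted at non-adjacent random positions.
#'
#' @param series a clean [rr_series()].
#' @param fraction proportion of beats to corrupt, in `[0, 0.2]`
#'   (beyond 20% is outside the correction design range).
#' @param seed integer seed.
#' @return A list with `series` (corrupted [rr_series()]) and
#'   `corrupted` (indices of altered beats).
#' @export
inject_ectopic_artifacts <- function(series, fraction, seed = 1) {
  check_number(fraction, "fraction", lower = 0)
  if (fraction > 0.2) {
    stop_validation(
      "ectopic fraction %.2f exceeds the 0.2 correction design range",
      fraction)
  }
  x <- as.numeric(series)
  n <- length(x)
  n_pairs <- floor(fraction * n / 2)
  if (n_pairs == 0) return(list(series = rr_series(x),
                                corrupted = integer()))
  set.seed(seed)
  candidates <- 2:(n - 2)
  starts <- integer(0)
  while (length(starts) < n_pairs && length(candidates)) {
    pick <- candidates[sample.int(length(candidates), 1L)]
    starts <- c(starts, pick)
    candidates <- setdiff(candidates, (pick - 2):(pick + 2))
  }
  if (length(starts) < n_pairs) {
    stop_validation("could not place %d non-adjacent ectopic pairs in %d beats",
                    n_pairs, n)
  }
  starts <- sort(starts)
  for (i in starts) {
    lo <- max(1L, i - 5L)
    hi <- min(n, i + 6L)
    local_mean <- mean(x[setdiff(lo:hi, c(i, i + 1L))])
    short <- 0.6 * local_mean
    shift <- x[i] - short
    x[i] <- short
    x[i + 1L] <- x[i + 1L] + shift
  }
  list(series = rr_series(x),
       corrupted = sort(c(starts, starts + 1L)))
}
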