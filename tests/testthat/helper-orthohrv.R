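# Shared test utilities. Oracles here are written independently of the
# package implementations they check (double loops, direct formulas).

# Brute-force RMSSD by explicit double loop over successive pairs.
rmssd_brute <- function(x) {
  acc <- 0
  for (i in seq_len(length(x) - 1)) {
    acc <- acc + (x[i + 1] - x[i])^2
  }
  sqrt(acc / (length(x) - 1))
}

# Direct periodogram band fraction of a known tachogram: fraction of
# total spectral power (raw FFT of the uniformly resampled, detrended
# signal, no windowing or segmenting) in [lo, hi] Hz relative to the
# union of both HRV bands.
band_fraction_oracle <- function(rr_ms, lo, hi, fs = 4) {
  tt <- cumsum(rr_ms) / 1000
  grid <- seq(tt[1], tt[length(tt)], by = 1 / fs)
  xi <- stats::spline(tt, rr_ms, xout = grid)$y
  xi <- stats::lsfit(grid, xi)$residuals
  n <- length(xi)
  sp <- Mod(stats::fft(xi))^2
  freq <- (seq_len(n) - 1) * fs / n
  keep <- seq_len(floor(n / 2))
  sp <- sp[keep]
  freq <- freq[keep]
  in_band <- function(a, b) sum(sp[freq >= a & freq <= b])
  in_band(lo, hi) / in_band(0.04, 0.40)
}

# A clean synthetic tachogram for QC tests: constant mean with mild
# high-frequency variability, safely below any correction threshold.
clean_tachogram <- function(n = 400, mean_rr = 800, wobble = 15,
                            seed = 1) {
  set.seed(seed)
  rr_series(mean_rr + wobble * sin(2 * pi * 0.25 * (1:n) * mean_rr / 1000) +
              rnorm(n, 0, 3))
}

the_eight <- c("vo2max", "training_load", "hr_max", "rpe",
               "perceived_fatigue", "doms", "sleep_quality", "stress")

r1_truth <- c(`(Intercept)` = 1249.37, vo2max = 12.32,
              training_load = 0.36, hr_max = -8.83, rpe = -5.90,
              perceived_fatigue = -28.41)
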