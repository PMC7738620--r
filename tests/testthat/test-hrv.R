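test_that("time-domain indices match hand-derived values", {
  idx <- time_domain_indices(rr_series(c(800, 810, 790, 805)))
  # sqrt((10^2 + 20^2 + 15^2)/3) computed by hand
  expect_equal(idx$rmssd, sqrt((100 + 400 + 225) / 3), tolerance = 1e-12)
  expect_equal(idx$ln_rmssd, log(idx$rmssd))
  expect_equal(idx$mean_rr, mean(c(800, 810, 790, 805)))

  const <- time_domain_indices(rr_series(rep(900, 300)))
  expect_equal(const$mean_rr, 900)
  expect_equal(const$mean_hr, 60000 / 900)
  expect_equal(const$rmssd, 0)
  expect_true(is.na(const$ln_rmssd))  # flagged missing, not -Inf

  expect_error(time_domain_indices(rr_series(1000)), "single-beat")
})

test_that("RMSSD agrees with a brute-force double loop on random series", {
  set.seed(42)
  for (i in 1:50) {
    x <- runif(sample(10:500, 1), 500, 1200)
    expect_equal(time_domain_indices(rr_series(x))$rmssd,
                 rmssd_brute(x), tolerance = 1e-9)
  }
})

test_that("RMSSD symmetries: time reversal and scaling of differences", {
  set.seed(7)
  for (i in 1:20) {
    x <- runif(100, 600, 1100)
    fwd <- time_domain_indices(rr_series(x))$rmssd
    expect_equal(time_domain_indices(rr_series(rev(x)))$rmssd, fwd)
    # scaling all successive differences by c scales RMSSD by exactly c
    c_scale <- runif(1, 0.2, 3)
    y <- x[1] + c_scale * cumsum(c(0, diff(x)))
    y <- y - min(y) + 400  # keep intervals physiologic/positive
    expect_equal(time_domain_indices(rr_series(y))$rmssd,
                 c_scale * fwd, tolerance = 1e-9)
  }
})

test_that("spectral band powers land in the modulated band", {
  # HF-only tachogram at 0.25 Hz
  hf <- simulate_rr_tachogram(900, 40, hf_share = 1, lf_share = 0,
                              seed = 2)
  sp <- spectral_powers(hf)
  expect_gt(sp$hf_nu, 0.95)
  expect_equal(sp$hf_nu + sp$lf_nu, 1)
  # agrees with an unwindowed direct-periodogram oracle
  expect_gt(band_fraction_oracle(as.numeric(hf), 0.15, 0.40), 0.95)

  # LF-only tachogram at 0.10 Hz
  lf <- simulate_rr_tachogram(900, 40, hf_share = 0, lf_share = 1,
                              seed = 2)
  sp_lf <- spectral_powers(lf)
  expect_gt(sp_lf$lf_nu, 0.95)
  expect_gt(band_fraction_oracle(as.numeric(lf), 0.04, 0.15), 0.95)

  # constant series: both bands at the numerical floor, nu undefined
  const <- spectral_powers(rr_series(rep(800, 500)))
  expect_lt(const$lf_abs + const$hf_abs, 1e-10)
  expect_true(is.na(const$lf_nu) && is.na(const$hf_nu))

  expect_error(spectral_powers(rr_series(rep(800, 50))), "segment")
})

test_that("integrated in-band power approximates A^2/2 for a pure sinusoid", {
  a <- 30
  rr <- simulate_rr_tachogram(1000, 0, seed = 1)  # constant base
  tt <- cumsum(as.numeric(rr)) / 1000
  mod <- rr_series(as.numeric(rr) + a * sin(2 * pi * 0.25 * tt))
  sp <- spectral_powers(mod)
  expect_equal(sp$hf_abs, a^2 / 2, tolerance = 0.15)
})

test_that("normalized units sum to one whenever band power is positive", {
  set.seed(9)
  for (i in 1:10) {
    rr <- simulate_rr_tachogram(runif(1, 700, 1100), runif(1, 15, 60),
                                hf_share = runif(1, 0.2, 0.7),
                                lf_share = runif(1, 0.1, 0.3),
                                seed = i)
    sp <- spectral_powers(rr)
    expect_gt(sp$lf_abs + sp$hf_abs, 0)
    expect_equal(sp$lf_nu + sp$hf_nu, 1, tolerance = 1e-12)
  }
})

test_that("orthostatic deltas are supine minus standing and antisymmetric", {
  sup <- list(mean_rr = 1000, rmssd = 50, ln_rmssd = log(50))
  sta <- list(mean_rr = 700, rmssd = 20, ln_rmssd = log(20))
  d <- orthostatic_deltas(sup, sta)
  expect_equal(d$delta_rr_mean, 300)
  expect_equal(d$delta_rmssd, 30)
  expect_equal(d$delta_ln_rmssd, log(50) - log(20))

  # identical phases give all-zero deltas
  d0 <- orthostatic_deltas(sup, sup)
  expect_equal(unlist(d0), c(delta_rr_mean = 0, delta_rmssd = 0,
                             delta_ln_rmssd = 0))

  # swapping phases negates every delta
  dswap <- orthostatic_deltas(sta, sup)
  expect_equal(dswap$delta_rr_mean, -d$delta_rr_mean)
  expect_equal(dswap$delta_rmssd, -d$delta_rmssd)
  expect_equal(dswap$delta_ln_rmssd, -d$delta_ln_rmssd)

  # undefined LnRMSSD in a phase propagates as missing, not -Inf
  sta_flat <- list(mean_rr = 700, rmssd = 0, ln_rmssd = NA_real_)
  expect_true(is.na(orthostatic_deltas(sup, sta_flat)$delta_ln_rmssd))
})

test_that("session_hrv produces one flat row with deltas consistent to phases", {
  sess <- simulate_orthostatic_rr(1000, 700, 45, 22, seed = 8)
  s <- assemble_session(sess$supine, sess$standing, "A03", 9,
                        threshold_ms = 250)
  row <- session_hrv(s)
  expect_equal(nrow(row), 1)
  expect_equal(row$delta_rr_mean, row$mean_rr_sup - row$mean_rr_sta)
  expect_equal(row$delta_rmssd, row$rmssd_sup - row$rmssd_sta)
  expect_identical(row$quality_flag, "ok")
})
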