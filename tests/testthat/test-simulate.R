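test_that("athlete profiles honour the configured distributions", {
  # zero-variance config collapses to identical mean profiles
  cfg0 <- sim_config(n_athletes = 3, seed = 1, vo2max_sd = 0,
                     hr_max_sd = 0, training_sd = 0, years_sd = 0)
  prof0 <- simulate_athletes(cfg0)
  expect_equal(prof0$vo2max, rep(53.6, 3))
  expect_equal(prof0$hr_max, rep(185.7, 3))
  expect_equal(prof0$training_load, rep(187.5, 3))

  # identical seed: byte-identical tables; different seed: different
  cfg <- sim_config(n_athletes = 10, seed = 99)
  expect_identical(simulate_athletes(cfg), simulate_athletes(cfg))
  expect_false(identical(simulate_athletes(cfg),
                         simulate_athletes(sim_config(n_athletes = 10,
                                                      seed = 100))))

  # replicate means concentrate on the configured population mean
  means <- vapply(1:200, function(i) {
    mean(simulate_athletes(sim_config(n_athletes = 10, seed = i))$vo2max)
  }, numeric(1))
  expect_lt(abs(mean(means) - 53.6), 3 * 5.2 / sqrt(2000))

  expect_error(simulate_athletes(sim_config(n_athletes = 0)),
               "n_athletes")
})

test_that("the default calendar lays out the multistage event", {
  cal <- build_event_calendar(sim_config())
  expect_equal(sum(cal$day_type == "stage"), 21)
  expect_equal(sum(cal$day_type == "baseline"), 4)
  expect_equal(sum(cal$day_type == "rest"), 2)
  expect_equal(sum(cal$day_type == "post"), 1)
  expect_equal(cal$day_index, 0:27)
  # stage distance is positive exactly on stage days
  expect_true(all((cal$stage_km > 0) == (cal$day_type == "stage")))
  # rest days sit after the configured stages
  expect_identical(cal$day_type[match(c(9, 15), cal$stage_number) + 1],
                   c("rest", "rest"))

  # degenerate calendar: no stages
  cal0 <- build_event_calendar(sim_config(n_stage = 0, n_baseline = 2))
  expect_setequal(unique(cal0$day_type), c("baseline", "post"))
})

test_that("latent fatigue follows the accumulation/decay recurrence", {
  expect_equal(fatigue_dynamics(c(0, 0, 0), 0.5, 1)$values, rep(0, 3))
  expect_equal(fatigue_dynamics(c(100, 0), 0.5, 1)$values, c(100, 50))

  # geometric-series closed form under constant load
  f <- fatigue_dynamics(rep(40, 400), 0.8, 0.5)$values
  expect_equal(f[400], 0.5 * 40 / (1 - 0.8), tolerance = 1e-6)

  # rest days strictly decrease positive fatigue
  f2 <- fatigue_dynamics(c(100, 100, 0, 0), 0.7, 1)$values
  expect_lt(f2[3], f2[2])
  expect_lt(f2[4], f2[3])

  expect_error(fatigue_dynamics(c(10, 20), 1, 1), "rho")
  expect_error(fatigue_dynamics(c(10, -5), 0.5, 1), "non-negative")
})

test_that("emitted observables reduce to the linear predictor without noise", {
  cfg <- sim_config(n_athletes = 1, seed = 5, noise_sd = 0,
                    coef = c(`(Intercept)` = 500, vo2max = 0,
                             training_load = 0, hr_max = 0, rpe = 0,
                             perceived_fatigue = 0))
  prof <- simulate_athletes(cfg)
  cal <- build_event_calendar(cfg)
  fat <- list(list(values = rep(0, nrow(cal))))
  rec <- emit_observables(prof, cal, fat, cfg)
  expect_equal(rec$delta_rr_true, rep(500, nrow(cal)))

  # misaligned fatigue series -> argument error
  expect_error(emit_observables(prof, cal,
                                list(list(values = rep(0, 3))), cfg),
               "calendar")
  expect_error(emit_observables(prof, cal, list(), cfg), "one fatigue")
})

test_that("generative worked example: cohort means, RPE 5, fatigue item 4", {
  cfg <- sim_config(n_athletes = 1, seed = 6, noise_sd = 0,
                    vo2max_sd = 0, hr_max_sd = 0, training_sd = 0,
                    years_sd = 0, stage_km_mean = 200, stage_km_sd = 0,
                    rpe_noise_sd = 0, item_noise_sd = 0,
                    n_baseline = 0, n_stage = 6)
  prof <- simulate_athletes(cfg)
  cal <- build_event_calendar(cfg)
  # overnight fatigue held at half the reference -> item 1 + 6*0.5 = 4
  fat <- list(list(values = rep(0.5 * cfg$fatigue_ref, nrow(cal))))
  rec <- emit_observables(prof, cal, fat, cfg)
  # steady state: stage days preceded by a 200-km stage (RPE 5)
  steady <- rec[rec$day_type == "stage" & rec$rpe_prev == 5, ]
  expect_gt(nrow(steady), 0)
  expect_equal(unique(steady$rpe), 5)
  expect_equal(unique(steady$perceived_fatigue), 4)
  expect_equal(unique(round(steady$delta_rr_true, 3)), 194.351)
})

test_that("OLS on the emitted cohort recovers the generative coefficients", {
  d <- simulate_regression_cohort(n = 10000, noise_sd = 30, seed = 13)
  fit <- fit_ols(delta_rr_mean ~ vo2max + training_load + hr_max +
                   rpe + perceived_fatigue, d)
  truth <- r1_truth[names(coef(fit))]
  expect_true(all(abs(coef(fit) - truth) <=
                    3 * fit$standard_errors[names(coef(fit))]))
})

test_that("tachogram synthesis hits its mean and RMSSD targets", {
  # degenerate: no modulation, no noise -> constant series
  flat <- simulate_rr_tachogram(800, 0, seed = 1)
  expect_equal(unique(as.numeric(flat)), 800)
  expect_equal(time_domain_indices(flat)$rmssd, 0)

  set.seed(20)
  for (i in 1:10) {
    m <- runif(1, 600, 1200)
    target <- runif(1, 10, 80)
    rr <- simulate_rr_tachogram(m, target, seed = i)
    expect_equal(mean(as.numeric(rr)), m, tolerance = 1e-9)
    realized <- time_domain_indices(rr)$rmssd
    expect_lt(abs(realized - target) / target, 0.10)
    expect_gte(sum(as.numeric(rr)) / 1000, 420)
  }

  # infeasible target: modulation would force RR <= 0
  expect_error(simulate_rr_tachogram(400, 300, seed = 1), "infeasible")
  expect_error(simulate_rr_tachogram(100, 10), "mean_rr")
})

test_that("orthostatic pair construction yields the requested delta", {
  sess <- simulate_orthostatic_rr(1000, 700, 45, 20, seed = 3)
  d <- orthostatic_deltas(time_domain_indices(sess$supine),
                          time_domain_indices(sess$standing))
  expect_lt(abs(d$delta_rr_mean - 300), 1)
  # pipeline-measured delta (correction + windowing) stays within 2 ms
  s <- assemble_session(sess$supine, sess$standing, threshold_ms = 250)
  row <- session_hrv(s, spectral = FALSE)
  expect_lt(abs(row$delta_rr_mean - 300), 2)
})

test_that("ectopic injection preserves time and floor arithmetic", {
  clean <- clean_tachogram(n = 400, seed = 30)
  # fraction 0: unchanged
  same <- inject_ectopic_artifacts(clean, 0, seed = 1)
  expect_equal(as.numeric(same$series), as.numeric(clean))

  # fraction 0.03 of 400 -> exactly 12 corrupted beats
  inj <- inject_ectopic_artifacts(clean, 0.03, seed = 2)
  expect_length(inj$corrupted, 12)
  # cumulative recording time unchanged
  expect_equal(sum(as.numeric(inj$series)), sum(as.numeric(clean)),
               tolerance = 1e-9)
  # corrupted beats really are premature: shortened to ~60% local mean
  shortened <- inj$corrupted[seq(1, 12, by = 2)]
  expect_true(all(as.numeric(inj$series)[shortened] <
                    0.75 * mean(as.numeric(clean))))

  expect_error(inject_ectopic_artifacts(clean, 0.25), "0.2")
})

test_that("correction round-trips injected ectopy", {
  clean <- clean_tachogram(n = 500, mean_rr = 850, seed = 31)
  inj <- inject_ectopic_artifacts(clean, 0.03, seed = 4)
  fixed <- correct_artifacts(inj$series, threshold_ms = 200)
  expect_lt(fixed$corrected_fraction, 0.05)
  expect_lt(abs(mean(as.numeric(fixed$series)) -
                  mean(as.numeric(clean))), 2)
})

test_that("cohort simulation is deterministic and shows rest-day rebound", {
  cfg <- sim_config(n_athletes = 6, seed = 14, n_stage = 10,
                    rest_after = c(4, 7))
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$profiles, sim2$profiles)

  # the deterministic part of the generated delta rebounds after each
  # rest day (no new load, overnight fatigue decays)
  cal <- sim1$calendar
  prev_type <- c(NA, cal$day_type[-nrow(cal)])
  rec <- merge(sim1$records,
               data.frame(day_index = cal$day_index, prev = prev_type))
  expect_gt(mean(rec$linear_predictor[rec$prev %in% "rest"]),
            mean(rec$linear_predictor[rec$prev %in% "stage"]))

  # TRIMP flows through the workload module: positive exactly on stages
  stage_days <- cal$day_type == "stage"
  expect_true(all(sim1$trimp[, stage_days] > 0))
  expect_true(all(sim1$trimp[, !stage_days] == 0))
})

test_that("rest-day rebound survives observation noise at cohort scale", {
  # enough athletes that the expected post-rest gap in the realized
  # deltas dominates the generative noise
  sim <- simulate_cohort(sim_config(n_athletes = 120, seed = 15))
  cal <- sim$calendar
  prev_type <- c(NA, cal$day_type[-nrow(cal)])
  rec <- merge(sim$records,
               data.frame(day_index = cal$day_index, prev = prev_type))
  post_rest <- rec$delta_rr_true[rec$prev %in% "rest"]
  post_stage <- rec$delta_rr_true[rec$prev %in% "stage"]
  expect_gt(mean(post_rest), mean(post_stage))
})
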