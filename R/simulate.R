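#' Simulation configuration for a synthetic multistage-event cohort
#'
#' Bundles every knob of the synthetic-data generator with defaults
#' describing a 10-athlete, 28-day grand-tour-style event: 4 baseline
#' days, 21 racing stages of ~200 km with rest days after stages 9 and
#' 15, and 1 post-event day. Athlete profiles are drawn from truncated
#' normals at the cohort means/SDs of well-trained female endurance
#' cyclists (VO2max 53.6 +/- 5.2 ml/min/kg, HRmax 185.7 +/- 7.2 bpm,
#' training volume 187.5 +/- 51.5 km/week). The generative truth for
#' the orthostatic mean-RR delta is the packaged `R1_deltaRR` equation
#' plus Gaussian noise.
#'
#' @param n_athletes number of athletes.
#' @param seed master seed; every stage draws from a named substream
#'   derived via [substream_seed()].
#' @param n_baseline,n_stage,n_post calendar structure (days).
#' @param rest_after stage numbers after which a rest day is inserted.
#' @param stage_km_mean,stage_km_sd,stage_km_min stage-distance
#'   distribution (normal, truncated below at `stage_km_min`).
#' @param vo2max_mean,vo2max_sd,hr_max_mean,hr_max_sd,training_mean,training_sd,years_mean,years_sd
#'   athlete-profile distributions.
#' @param coef named generative coefficients for the mean-RR delta:
#'   `(Intercept)`, `vo2max`, `training_load`, `hr_max`, `rpe`,
#'   `perceived_fatigue` (defaults: the packaged `R1_deltaRR`
#'   equation).
#' @param noise_sd residual SD of the generated delta (ms).
#' @param rho day-to-day carryover fraction of latent fatigue in
#'   `[0, 1)`.
#' @param kappa workload-to-fatigue gain (fatigue units per TRIMP
#'   point).
#' @param fatigue_ref fatigue level treated as "fully fatigued" when
#'   binning into the 1-7 questionnaire items; default: the
#'   steady-state fatigue under a typical 800-point daily TRIMP,
#'   `kappa * 800 / (1 - rho)`.
#' @param item_noise_sd SD of the noise added to each questionnaire
#'   item before rounding to the 1-7 scale.
#' @param orientation `"fatigue"` (default: higher latent fatigue gives
#'   higher item scores, matching how the generative delta equation
#'   uses the perceived-fatigue item) or `"wellbeing"` (items reversed:
#'   1 = poor, 7 = very good).
#' @param rpe_per_km,rpe_noise_sd RPE generation: monotone in stage
#'   distance plus noise, clamped to the 0-10 scale.
#' @param speed_kmh,trace_sample_s stage HR-trace generation: riding
#'   speed fixing stage duration, and the trace sampling interval (s).
#' @param intensity_mean,intensity_sd mean within-stage exercise
#'   intensity as a fraction of HRmax.
#' @param resp_freq,lf_freq tachogram modulation frequencies (Hz),
#'   inside the HF `[0.15, 0.40]` and LF `[0.04, 0.15)` bands.
#' @param hf_share,lf_share fraction of the squared RMSSD target
#'   carried by the HF and LF sinusoids (the remainder is white
#'   noise).
#' @param mean_rr_standing_base,mean_rr_standing_sd per-athlete
#'   standing mean RR baseline (ms).
#' @param rmssd_standing_mean,rmssd_supine_base supine/standing RMSSD
#'   targets (ms); supine RMSSD declines with latent fatigue.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_athletes = 10,
                       seed = 1,
                       n_baseline = 4, n_stage = 21, n_post = 1,
                       rest_after = c(9, 15),
                       stage_km_mean = 200, stage_km_sd = 40,
                       stage_km_min = 50,
                       vo2max_mean = 53.6, vo2max_sd = 5.2,
                       hr_max_mean = 185.7, hr_max_sd = 7.2,
                       training_mean = 187.5, training_sd = 51.5,
                       years_mean = 14, years_sd = 8.9,
                       coef = c(`(Intercept)` = 1249.37, vo2max = 12.32,
                                training_load = 0.36, hr_max = -8.83,
                                rpe = -5.90, perceived_fatigue = -28.41),
                       noise_sd = 100,
                       rho = 0.75, kappa = 0.02, fatigue_ref = NULL,
                       item_noise_sd = 0.8,
                       orientation = c("fatigue", "wellbeing"),
                       rpe_per_km = 1 / 40, rpe_noise_sd = 0.7,
                       speed_kmh = 28.8, trace_sample_s = 60,
                       intensity_mean = 0.65, intensity_sd = 0.04,
                       resp_freq = 0.25, lf_freq = 0.10,
                       hf_share = 0.65, lf_share = 0.25,
                       mean_rr_standing_base = 650,
                       mean_rr_standing_sd = 40,
                       rmssd_standing_mean = 30,
                       rmssd_supine_base = 65) {
  check_number(n_athletes, "n_athletes", lower = 1)
  check_number(rho, "rho", lower = 0)
  if (rho >= 1) stop_validation("`rho` must be in [0, 1)")
  check_number(kappa, "kappa", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(resp_freq, "resp_freq", lower = 0.15, upper = 0.40)
  check_number(lf_freq, "lf_freq", lower = 0.04)
  if (lf_freq >= 0.15) stop_validation("`lf_freq` must be in [0.04, 0.15)")
  for (s in c("stage_km_sd", "vo2max_sd", "hr_max_sd", "training_sd",
              "years_sd", "item_noise_sd", "rpe_noise_sd",
              "intensity_sd", "mean_rr_standing_sd")) {
    check_number(get(s), s, lower = 0)
  }
  if (hf_share < 0 || lf_share < 0 || hf_share + lf_share > 1) {
    stop_validation("hf_share and lf_share must be >= 0 and sum to <= 1")
  }
  if (is.null(fatigue_ref)) fatigue_ref <- kappa * 800 / (1 - rho)
  cfg <- as.list(environment())
  cfg$orientation <- match.arg(orientation)
  structure(cfg, class = "sim_config")
}

#' Draw synthetic athlete profiles
#'
#' Profiles are drawn from truncated normal distributions at the
#' configured means/SDs (VO2max above 20 ml/min/kg, HRmax within
#' 120-250 bpm, training volume and experience non-negative). With all
#' SDs zero the draw collapses to identical mean profiles.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with one row per athlete: `athlete_id`,
#'   `vo2max`, `hr_max`, `training_load`, `years_experience`.
#' @export
simulate_athletes <- function(config = sim_config()) {
  n <- config$n_athletes
  check_number(n, "n_athletes", lower = 1)
  set.seed(substream_seed(config$seed, "athletes"))
  data.frame(
    athlete_id = sprintf("A%02d", seq_len(n)),
    vo2max = rtruncnorm(n, config$vo2max_mean, config$vo2max_sd,
                        lower = 20),
    hr_max = rtruncnorm(n, config$hr_max_mean, config$hr_max_sd,
                        lower = 120, upper = 250),
    training_load = rtruncnorm(n, config$training_mean,
                               config$training_sd, lower = 0),
    years_experience = round(rtruncnorm(n, config$years_mean,
                                        config$years_sd, lower = 2)),
    stringsAsFactors = FALSE)
}

#' Build the event calendar
#'
#' Lays out baseline days, racing stages with rest days inserted after
#' the configured stage numbers, and post-event days, with one stage
#' distance drawn per stage (shared by all athletes, who ride the same
#' route).
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with `day_index` (0-based), `day_type`
#'   (`baseline`/`stage`/`rest`/`post`), `stage_number` (NA off
#'   stages) and `stage_km` (0 on non-stage days).
#' @export
build_event_calendar <- function(config = sim_config()) {
  for (f in c("n_baseline", "n_stage", "n_post")) {
    check_number(config[[f]], f, lower = 0)
  }
  set.seed(substream_seed(config$seed, "calendar"))
  types <- rep("baseline", config$n_baseline)
  stage_no <- rep(NA_integer_, config$n_baseline)
  if (config$n_stage > 0) {
    for (s in seq_len(config$n_stage)) {
      types <- c(types, "stage")
      stage_no <- c(stage_no, s)
      if (s %in% config$rest_after && s < config$n_stage) {
        types <- c(types, "rest")
        stage_no <- c(stage_no, NA_integer_)
      }
    }
  }
  types <- c(types, rep("post", config$n_post))
  stage_no <- c(stage_no, rep(NA_integer_, config$n_post))
  km <- numeric(length(types))
  is_stage <- types == "stage"
  km[is_stage] <- rtruncnorm(sum(is_stage), config$stage_km_mean,
                             config$stage_km_sd,
                             lower = config$stage_km_min)
  data.frame(day_index = seq_along(types) - 1L, day_type = types,
             stage_number = stage_no, stage_km = km,
             stringsAsFactors = FALSE)
}

#' Latent fatigue accumulation/decay dynamics
#'
#' A first-order linear recurrence operationalising accumulated
#' fatigue: starting from `F[0] = 0`,
#' `F[t] = rho * F[t-1] + kappa * TRIMP[t]`. With zero workload the
#' state decays geometrically by `rho`, so rest days strictly decrease
#' fatigue; under a constant workload `c` it converges to
#' `kappa * c / (1 - rho)`.
#'
#' @param trimp_series per-day TRIMP values (>= 0).
#' @param rho carryover fraction in `[0, 1)`.
#' @param kappa workload-to-fatigue gain (>= 0).
#' @return A list of class `latent_fatigue` with `values` (one per
#'   day), `rho` and `kappa`.
#' @examples
#' fatigue_dynamics(c(100, 0), rho = 0.5, kappa = 1)$values  # 100, 50
#' @export
fatigue_dynamics <- function(trimp_series, rho, kappa) {
  check_number(rho, "rho", lower = 0)
  if (rho >= 1) stop_validation("`rho` must be in [0, 1)")
  check_number(kappa, "kappa", lower = 0)
  if (any(is.na(trimp_series)) || any(trimp_series < 0)) {
    stop_validation("TRIMP values must be non-negative and non-missing")
  }
  f <- numeric(length(trimp_series))
  prev <- 0
  for (t in seq_along(trimp_series)) {
    prev <- rho * prev + kappa * trimp_series[t]
    f[t] <- prev
  }
  structure(list(values = f, rho = rho, kappa = kappa),
            class = "latent_fatigue")
}

#' Simulate a within-stage heart-rate trace
#'
#' A uniformly sampled HR trace for one racing stage: exercise
#' intensity (fraction of HRmax) follows a slow within-stage drift
#' plus sample noise, clamped to a plausible 45-98% band. Stage
#' duration follows from distance at the configured riding speed.
#'
#' @param stage_km stage distance (km).
#' @param hr_max the athlete's maximal heart rate (bpm).
#' @param config a [sim_config()].
#' @param seed integer seed for this trace.
#' @return A `data.frame` with `time_s`, `hr_bpm`.
#' @export
simulate_hr_trace <- function(stage_km, hr_max, config = sim_config(),
                              seed = 1) {
  check_number(stage_km, "stage_km", lower = 1)
  set.seed(seed)
  duration_s <- stage_km / config$speed_kmh * 3600
  tt <- seq(0, duration_s, by = config$trace_sample_s)
  base <- rtruncnorm(1, config$intensity_mean, config$intensity_sd,
                     lower = 0.5, upper = 0.9)
  drift <- 0.08 * sin(2 * pi * tt / max(duration_s, 1) * 1.5)
  frac <- clamp(base + drift + stats::rnorm(length(tt), 0, 0.05),
                0.45, 0.98)
  data.frame(time_s = tt, hr_bpm = frac * hr_max)
}

#' Emit per-athlete-day observable records from the latent states
#'
#' Converts profiles, calendar, per-athlete TRIMP and latent fatigue
#' into the daily observables. All morning measurements reflect the
#' previous day's exertion and the overnight fatigue state: the
#' questionnaire items bin the \emph{lagged} latent fatigue through a
#' fixed reference scale onto 1-7 (with item noise), and the
#' generative orthostatic mean-RR delta applies the configured linear
#' predictor to the athlete covariates, the previous day's RPE (0 when
#' the previous day had no stage) and the perceived-fatigue item, plus
#' Gaussian noise. The recorded `rpe` column is the same-day stage
#' rating (monotone in stage distance plus noise, clamped to 0-10,
#' absent off stages), as collected after each stage. Target
#' supine/standing mean RR and RMSSD values consistent with the
#' generated delta are attached for tachogram synthesis.
#'
#' @param profiles output of [simulate_athletes()].
#' @param calendar output of [build_event_calendar()].
#' @param fatigue list of [fatigue_dynamics()] results, one per
#'   athlete, each aligned to the calendar.
#' @param config a [sim_config()].
#' @param trimp optional list of per-athlete daily TRIMP vectors
#'   (recorded in the output when given).
#' @return A `data.frame` of daily records, one row per athlete-day.
#' @export
emit_observables <- function(profiles, calendar, fatigue,
                             config = sim_config(), trimp = NULL) {
  n_ath <- nrow(profiles)
  n_day <- nrow(calendar)
  if (length(fatigue) != n_ath) {
    stop_validation("need one fatigue series per athlete (%d != %d)",
                    length(fatigue), n_ath)
  }
  for (i in seq_len(n_ath)) {
    if (length(fatigue[[i]]$values) != n_day) {
      stop_validation(
        "fatigue series for athlete %d has %d days, calendar has %d",
        i, length(fatigue[[i]]$values), n_day)
    }
  }
  set.seed(substream_seed(config$seed, "observables"))
  rows <- vector("list", n_ath)
  for (i in seq_len(n_ath)) {
    prof <- profiles[i, ]
    f <- fatigue[[i]]$values
    ## morning state: overnight fatigue carried over from yesterday
    f_morning <- c(0, f[-n_day])
    fstd <- clamp(f_morning / config$fatigue_ref, 0, 1)
    is_stage <- calendar$day_type == "stage"
    rpe <- rep(NA_real_, n_day)
    rpe[is_stage] <- clamp(
      round(calendar$stage_km[is_stage] * config$rpe_per_km +
              stats::rnorm(sum(is_stage), 0, config$rpe_noise_sd), 1),
      0, 10)
    item <- function() {
      raw <- clamp(round(1 + 6 * fstd +
                           stats::rnorm(n_day, 0, config$item_noise_sd)),
                   1, 7)
      if (config$orientation == "wellbeing") 8 - raw else raw
    }
    perceived_fatigue <- item()
    sleep_quality <- item()
    doms <- item()
    stress <- item()
    ## yesterday's exertion drives this morning's delta
    rpe_prev <- c(0, ifelse(is.na(rpe), 0, rpe)[-n_day])
    cf <- config$coef
    lin <- cf[["(Intercept)"]] +
      cf[["vo2max"]] * prof$vo2max +
      cf[["training_load"]] * prof$training_load +
      cf[["hr_max"]] * prof$hr_max +
      cf[["rpe"]] * rpe_prev +
      cf[["perceived_fatigue"]] * perceived_fatigue
    delta_rr <- lin + stats::rnorm(n_day, 0, config$noise_sd)
    sta_base <- rtruncnorm(1, config$mean_rr_standing_base,
                           config$mean_rr_standing_sd,
                           lower = 450, upper = 1000)
    mean_rr_standing <- clamp(sta_base + stats::rnorm(n_day, 0, 10),
                              310, 1500)
    mean_rr_supine <- clamp(mean_rr_standing + delta_rr, 310, 1990)
    rmssd_supine <- clamp(config$rmssd_supine_base - 25 * fstd +
                            stats::rnorm(n_day, 0, 4), 8, 150)
    rmssd_standing <- clamp(config$rmssd_standing_mean +
                              stats::rnorm(n_day, 0, 4), 5, 100)
    rows[[i]] <- data.frame(
      athlete_id = prof$athlete_id,
      day_index = calendar$day_index,
      day_type = calendar$day_type,
      stage_km = calendar$stage_km,
      vo2max = prof$vo2max,
      hr_max = prof$hr_max,
      training_load = prof$training_load,
      trimp = if (is.null(trimp)) NA_real_ else trimp[[i]],
      rpe = rpe,
      rpe_prev = rpe_prev,
      perceived_fatigue = perceived_fatigue,
      sleep_quality = sleep_quality,
      doms = doms,
      stress = stress,
      wb = perceived_fatigue + sleep_quality + doms + stress,
      latent_fatigue = f,
      delta_rr_true = delta_rr,
      linear_predictor = lin,
      mean_rr_supine_target = mean_rr_supine,
      mean_rr_standing_target = mean_rr_standing,
      rmssd_supine_target = rmssd_supine,
      rmssd_standing_target = rmssd_standing,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic event cohort
#'
#' End-to-end generator: athlete profiles, event calendar, per-stage
#' HR traces (from which daily TRIMP is computed through the workload
#' module), latent fatigue, and the daily observable records. All
#' randomness flows from `config$seed` through named substreams, so
#' identical configurations reproduce byte-identical cohorts.
#'
#' @param config a [sim_config()].
#' @param keep_traces retain the simulated HR traces in the result
#'   (they are regenerated deterministically otherwise).
#' @return A list of class `cohort_sim`: `profiles`, `calendar`,
#'   `records`, `trimp` (athletes x days matrix), `ground_truth`
#'   (generative coefficients, noise SD, latent fatigue), `config`,
#'   and optionally `traces`.
#' @export
simulate_cohort <- function(config = sim_config(), keep_traces = FALSE) {
  profiles <- simulate_athletes(config)
  calendar <- build_event_calendar(config)
  n_ath <- nrow(profiles)
  n_day <- nrow(calendar)
  trimp <- matrix(0, n_ath, n_day)
  traces <- if (keep_traces) list() else NULL
  for (i in seq_len(n_ath)) {
    for (d in seq_len(n_day)) {
      if (calendar$day_type[d] == "stage") {
        tr <- simulate_hr_trace(
          calendar$stage_km[d], profiles$hr_max[i], config,
          seed = substream_seed(config$seed,
                                sprintf("trace_%d_%d", i, d)))
        trimp[i, d] <- edwards_trimp(
          hr_zone_durations(tr$time_s, tr$hr_bpm, profiles$hr_max[i]))
        if (keep_traces) {
          traces[[sprintf("%s_day%02d", profiles$athlete_id[i],
                          calendar$day_index[d])]] <- tr
        }
      }
    }
  }
  fatigue <- lapply(seq_len(n_ath), function(i) {
    fatigue_dynamics(trimp[i, ], config$rho, config$kappa)
  })
  records <- emit_observables(profiles, calendar, fatigue, config,
                              trimp = lapply(seq_len(n_ath),
                                             function(i) trimp[i, ]))
  structure(list(
    profiles = profiles, calendar = calendar, records = records,
    trimp = trimp,
    ground_truth = list(coef = config$coef, noise_sd = config$noise_sd,
                        rho = config$rho, kappa = config$kappa,
                        latent_fatigue = lapply(fatigue, `[[`, "values")),
    config = config, traces = traces
  ), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d athletes x %d days (%d stages), seed %s\n",
    nrow(x$profiles), nrow(x$calendar),
    sum(x$calendar$day_type == "stage"), format(x$config$seed)))
  invisible(x)
}

#' Simulate a flat regression cohort with known coefficients
#'
#' Draws independent records of the eight candidate indicators at
#' realistic marginals (profile covariates at the cohort means/SDs,
#' RPE uniform on 0-10, questionnaire items uniform on 1-7) and a
#' response from a configured linear truth plus Gaussian noise. This
#' is the ground-truth fixture for coefficient-recovery and
#' model-selection experiments, where the estimator must see many
#' more records than one event provides.
#'
#' @param n number of records.
#' @param coef named generative coefficients; names must be
#'   `(Intercept)` plus a subset of the eight candidates. Defaults to
#'   the packaged `R1_deltaRR` truth (5 active predictors among 8
#'   candidates).
#' @param noise_sd residual SD of the response.
#' @param seed integer seed.
#' @param response name of the generated response column.
#' @return A `data.frame` with the eight candidate columns and the
#'   response.
#' @export
simulate_regression_cohort <- function(n = 2000,
                                       coef = c(`(Intercept)` = 1249.37,
                                                vo2max = 12.32,
                                                training_load = 0.36,
                                                hr_max = -8.83,
                                                rpe = -5.90,
                                                perceived_fatigue = -28.41),
                                       noise_sd = 30, seed = 1,
                                       response = "delta_rr_mean") {
  check_number(n, "n", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  set.seed(substream_seed(seed, "regression_cohort"))
  d <- data.frame(
    vo2max = stats::rnorm(n, 53.6, 5.2),
    training_load = rtruncnorm(n, 187.5, 51.5, lower = 0),
    hr_max = stats::rnorm(n, 185.7, 7.2),
    rpe = round(stats::runif(n, 0, 10), 1),
    perceived_fatigue = sample(1:7, n, replace = TRUE),
    doms = sample(1:7, n, replace = TRUE),
    sleep_quality = sample(1:7, n, replace = TRUE),
    stress = sample(1:7, n, replace = TRUE))
  bad <- setdiff(names(coef), c("(Intercept)", names(d)))
  if (length(bad)) {
    stop_validation("unknown coefficient name(s): %s",
                    paste(bad, collapse = ", "))
  }
  y <- rep(if ("(Intercept)" %in% names(coef)) coef[["(Intercept)"]]
           else 0, n)
  for (nm in setdiff(names(coef), "(Intercept)")) {
    y <- y + coef[[nm]] * d[[nm]]
  }
  d[[response]] <- y + stats::rnorm(n, 0, noise_sd)
  d
}
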