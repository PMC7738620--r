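#' Write a simulated cohort's raw exchange files
#'
#' Materialises a [simulate_cohort()] result as the standard exchange
#' set: per-session RR text files (one interval in ms per line) with a
#' session manifest CSV, per-stage HR-trace CSVs with a trace
#' manifest, profile/calendar/questionnaire/RPE CSVs, the cohort
#' record table, and a ground-truth JSON holding the generative
#' coefficients and latent states.
#'
#' @param sim a `cohort_sim` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest `data.frame`, invisibly.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(file.path(dir, "rr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(sim$profiles, "profiles.csv")
  wcsv(sim$calendar, "calendar.csv")
  rec <- sim$records
  wcsv(rec[c("athlete_id", "day_index", "perceived_fatigue",
             "sleep_quality", "doms", "stress")], "questionnaire.csv")
  wcsv(rec[c("athlete_id", "day_index", "rpe")], "rpe.csv")
  wcsv(rec, "cohort_true.csv")

  cfg <- sim$config
  manifest <- NULL
  for (r in seq_len(nrow(rec))) {
    sess <- simulate_orthostatic_rr(
      rec$mean_rr_supine_target[r], rec$mean_rr_standing_target[r],
      rec$rmssd_supine_target[r], rec$rmssd_standing_target[r],
      resp_freq = cfg$resp_freq, lf_freq = cfg$lf_freq,
      hf_share = cfg$hf_share, lf_share = cfg$lf_share,
      seed = substream_seed(cfg$seed, sprintf("tachogram_%d", r)))
    for (ph in c("supine", "standing")) {
      rel <- file.path("rr", sprintf("%s_day%02d_%s.txt",
                                     rec$athlete_id[r],
                                     rec$day_index[r], ph))
      write_rr_text(sess[[ph]], file.path(dir, rel))
      manifest <- rbind(manifest, data.frame(
        athlete_id = rec$athlete_id[r], day_index = rec$day_index[r],
        phase = ph, path = rel, stringsAsFactors = FALSE))
    }
  }
  wcsv(manifest, "manifest.csv")

  tr_manifest <- NULL
  for (i in seq_len(nrow(sim$profiles))) {
    for (d in seq_len(nrow(sim$calendar))) {
      if (sim$calendar$day_type[d] != "stage") next
      tr <- simulate_hr_trace(
        sim$calendar$stage_km[d], sim$profiles$hr_max[i], cfg,
        seed = substream_seed(cfg$seed, sprintf("trace_%d_%d", i, d)))
      rel <- file.path("traces", sprintf("%s_day%02d.csv",
                                         sim$profiles$athlete_id[i],
                                         sim$calendar$day_index[d]))
      utils::write.csv(tr, file.path(dir, rel), row.names = FALSE)
      tr_manifest <- rbind(tr_manifest, data.frame(
        athlete_id = sim$profiles$athlete_id[i],
        day_index = sim$calendar$day_index[d],
        stage_km = sim$calendar$stage_km[d],
        path = rel, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(tr_manifest)) wcsv(tr_manifest, "traces.csv")
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_defaults <- function() {
  list(simulate = TRUE, seed = 1, sim = list(),
       threshold_ms = 450, window_s = 300, reject_at = 0.05,
       spectral = TRUE, resample_hz = 4, segment_s = 150,
       overlap_fraction = 0.5,
       response = "delta_rr_mean",
       candidates = c("vo2max", "training_load", "hr_max", "rpe",
                      "perceived_fatigue", "doms", "sleep_quality",
                      "stress"),
       predict_model = "R1_deltaRR", margin = 0, verbose = TRUE)
}

#' Run the full stress-recovery monitoring pipeline
#'
#' Orchestrates every stage end-to-end from one configuration:
#' (optional) cohort simulation with raw-file export, session quality
#' control, HRV indices and orthostatic deltas, stage workload
#' (zone minutes and Edwards TRIMP), well-being scoring, the
#' correlation surface, the exhaustive AIC subset search, and
#' predicted-vs-measured recovery flagging. Every intermediate table
#' is written as CSV under `out_dir` together with a JSON run manifest
#' (seed, configuration, row and rejection counts) sufficient to
#' reproduce the run. Reruns with an identical configuration and seed
#' are byte-identical.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised keys (defaults in parentheses): `out_dir` (required),
#'   `simulate` (TRUE), `seed` (1), `sim` (list passed to
#'   [sim_config()]), `input_dir` (directory of raw files when
#'   `simulate` is FALSE, laid out as written by
#'   [write_cohort_files()]), `threshold_ms` (450), `window_s` (300),
#'   `reject_at` (0.05), `spectral` (TRUE), `resample_hz`,
#'   `segment_s`, `overlap_fraction`, `response` (`delta_rr_mean`),
#'   `candidates` (the eight indicators), `predict_model`
#'   (`R1_deltaRR`), `margin` (0), `verbose` (TRUE).
#' @return Invisibly, a list with the cohort table, the
#'   `subset_search` object, the correlation table, the prediction
#'   table, and the paths of all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_validation("config file not found: %s", config)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) stop_validation("config must set `out_dir`")
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  ## fail fast: resolve the input directory before any stage runs
  if (isTRUE(cfg$simulate)) {
    raw_dir <- file.path(cfg$out_dir, "raw")
  } else {
    raw_dir <- cfg$input_dir
    if (is.null(raw_dir) || !dir.exists(raw_dir)) {
      stop_validation("input_dir does not exist: %s",
                      if (is.null(raw_dir)) "<unset>" else raw_dir)
    }
    for (f in c("manifest.csv", "profiles.csv", "calendar.csv",
                "questionnaire.csv", "rpe.csv")) {
      if (!file.exists(file.path(raw_dir, f))) {
        stop_validation("missing input file: %s", file.path(raw_dir, f))
      }
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wcsv <- function(d, f) {
    p <- file.path(cfg$out_dir, f)
    utils::write.csv(d, p, row.names = FALSE)
    paths[[sub("[.]csv$", "", f)]] <<- p
    p
  }

  if (isTRUE(cfg$simulate)) {
    sim_cfg <- do.call(sim_config, utils::modifyList(
      cfg$sim, list(seed = cfg$seed)))
    say("stage simulate: %d athletes, seed %d",
        sim_cfg$n_athletes, cfg$seed)
    sim <- simulate_cohort(sim_cfg)
    write_cohort_files(sim, raw_dir)
    say("stage simulate: wrote %d daily records to %s",
        nrow(sim$records), raw_dir)
  }
  rcsv <- function(f) utils::read.csv(file.path(raw_dir, f),
                                      stringsAsFactors = FALSE)
  manifest <- rcsv("manifest.csv")
  profiles <- rcsv("profiles.csv")
  calendar <- rcsv("calendar.csv")
  questionnaire <- rcsv("questionnaire.csv")
  rpe_tab <- rcsv("rpe.csv")

  ## sessions + hrv
  keys <- unique(manifest[c("athlete_id", "day_index")])
  hrv_rows <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sub <- manifest[manifest$athlete_id == keys$athlete_id[k] &
                      manifest$day_index == keys$day_index[k], ]
    get_phase <- function(ph) {
      row <- sub[sub$phase == ph, ]
      if (nrow(row) != 1L) {
        stop_validation("sessions stage: athlete %s day %d has %d %s file(s)",
                        keys$athlete_id[k], keys$day_index[k],
                        nrow(row), ph)
      }
      read_rr_text(file.path(raw_dir, row$path))
    }
    sess <- assemble_session(get_phase("supine"), get_phase("standing"),
                             athlete_id = keys$athlete_id[k],
                             day_index = keys$day_index[k],
                             threshold_ms = cfg$threshold_ms,
                             window_s = cfg$window_s,
                             reject_at = cfg$reject_at)
    hrv_rows[[k]] <- session_hrv(sess, spectral = cfg$spectral,
                                 resample_hz = cfg$resample_hz,
                                 segment_s = cfg$segment_s,
                                 overlap_fraction = cfg$overlap_fraction)
  }
  hrv <- do.call(rbind, hrv_rows)
  say("stage sessions/hrv: %d sessions, %d rejected by the 5%% rule",
      nrow(hrv), sum(hrv$quality_flag == "rejected"))
  wcsv(hrv, "hrv.csv")

  ## workload
  workload <- NULL
  traces_path <- file.path(raw_dir, "traces.csv")
  if (file.exists(traces_path)) {
    tr_manifest <- utils::read.csv(traces_path, stringsAsFactors = FALSE)
    wl_rows <- lapply(seq_len(nrow(tr_manifest)), function(i) {
      tr <- utils::read.csv(file.path(raw_dir, tr_manifest$path[i]),
                            stringsAsFactors = FALSE)
      hrm <- profiles$hr_max[match(tr_manifest$athlete_id[i],
                                   profiles$athlete_id)]
      rpe_i <- rpe_tab$rpe[rpe_tab$athlete_id == tr_manifest$athlete_id[i] &
                             rpe_tab$day_index == tr_manifest$day_index[i]]
      cbind(tr_manifest[i, c("athlete_id", "day_index")],
            stage_workload(tr$time_s, tr$hr_bpm, hrm,
                           rpe = if (length(rpe_i)) rpe_i[1L] else NA,
                           stage_km = tr_manifest$stage_km[i]))
    })
    workload <- do.call(rbind, wl_rows)
    say("stage workload: %d stage records, mean TRIMP %.0f",
        nrow(workload), mean(workload$trimp))
    wcsv(workload, "workload.csv")
  }

  ## wellbeing
  wbt <- questionnaire
  wbt$wb <- wb_score(wbt$perceived_fatigue, wbt$sleep_quality,
                     wbt$doms, wbt$stress)
  wb_rows <- lapply(split(wbt, wbt$athlete_id), function(sub) {
    d <- delta_wb_series(sub$day_index, sub$wb)
    merge(sub, d$deltas, by = "day_index", all.x = TRUE)
  })
  wellbeing <- do.call(rbind, wb_rows)
  rownames(wellbeing) <- NULL
  wcsv(wellbeing, "wellbeing.csv")
  wb_train <- wb_vs_training(wellbeing, profiles)
  wcsv(wb_train$athletes, "wb_vs_training.csv")

  ## cohort assembly
  cohort <- merge(hrv, wellbeing, by = c("athlete_id", "day_index"),
                  all.x = TRUE)
  if (!is.null(workload)) {
    cohort <- merge(cohort,
                    workload[c("athlete_id", "day_index", "trimp",
                               "rpe", "stage_km")],
                    by = c("athlete_id", "day_index"), all.x = TRUE)
  } else {
    cohort <- merge(cohort, rpe_tab, by = c("athlete_id", "day_index"),
                    all.x = TRUE)
  }
  cohort <- merge(cohort, profiles, by = "athlete_id", all.x = TRUE)
  cohort <- cohort[order(cohort$athlete_id, cohort$day_index), ]
  rownames(cohort) <- NULL
  wcsv(cohort, "cohort.csv")
  say("stage cohort: %d athlete-day rows", nrow(cohort))

  ## correlation surface
  idx_cols <- intersect(
    c("mean_rr_sup", "mean_rr_sta", "rmssd_sup", "rmssd_sta",
      "delta_rr_mean", "delta_rmssd", "delta_ln_rmssd",
      "lf_nu_sup", "hf_nu_sup", "lf_abs_sup", "hf_abs_sup",
      "lf_hf_ratio_sup"),
    names(cohort))
  ind_cols <- intersect(
    c("stage_km", "trimp", "rpe", "perceived_fatigue", "doms",
      "sleep_quality", "stress"),
    names(cohort))
  correlations <- correlation_table(cohort, idx_cols, ind_cols)
  wcsv(correlations, "correlations.csv")

  ## exhaustive subset selection
  search <- best_subset_search(cfg$response, cohort,
                               candidates = cfg$candidates)
  mt <- search$table
  mt$coefficients <- vapply(search$fits, function(f) {
    if (is.null(f$coefficients)) return(NA_character_)
    paste(sprintf("%s=%.6g", names(f$coefficients), f$coefficients),
          collapse = ";")
  }, character(1))
  wcsv(mt, "model_table.csv")
  say("stage select-models: %d models, best: %s (AIC %.1f)",
      nrow(mt), mt$predictors[1L], mt$aic[1L])

  ## prediction + recovery flagging with the packaged equation
  pm <- published_model(cfg$predict_model)
  pred_rows <- cohort[cohort$quality_flag == "ok", , drop = FALSE]
  pred_rows <- pred_rows[stats::complete.cases(
    pred_rows[intersect(pm$predictor_names, names(pred_rows))]), ,
    drop = FALSE]
  predictions <- NULL
  if (nrow(pred_rows) &&
      all(pm$predictor_names %in% names(pred_rows))) {
    predicted <- suppressWarnings(
      predict(pm, pred_rows[pm$predictor_names]))
    predictions <- data.frame(
      athlete_id = pred_rows$athlete_id,
      day_index = pred_rows$day_index,
      measured = pred_rows[[pm$response_name]],
      predicted = predicted,
      status = flag_recovery(pred_rows[[pm$response_name]], predicted,
                             cfg$margin),
      stringsAsFactors = FALSE)
    wcsv(predictions, "predictions.csv")
    say("stage predict: %d days flagged imbalance of %d",
        sum(predictions$status == "imbalance"), nrow(predictions))
  }

  run_manifest <- list(
    package = "orthohrv",
    version = as.character(utils::packageVersion("orthohrv")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "verbose")],
    n_sessions = nrow(hrv),
    n_rejected = sum(hrv$quality_flag == "rejected"),
    n_cohort_rows = nrow(cohort),
    n_models = nrow(mt))
  jsonlite::write_json(run_manifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, search = search,
                 correlations = correlations,
                 predictions = predictions, paths = paths))
}
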