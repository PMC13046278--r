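#' Pipeline run configuration
#'
#' Bundles every stage configuration plus run-level options. Any element
#' can be overridden via `overrides` (a nested list merged over the
#' defaults, e.g. from a YAML file).
#'
#' @param sim [sim_config()] for the synthetic surgical cohort.
#' @param resample [resample_config()].
#' @param cleaning [cleaning_config()].
#' @param label [label_config()] (its `horizon` is the pipeline horizon).
#' @param model [model_config()] for the Transformer.
#' @param renal [renal_sim_config()] for the nested renal cohort.
#' @param spec [feature_spec()].
#' @param train_frac Patient-level training fraction.
#' @param threshold_strategy,threshold_target Decision-threshold selection
#'   on the internal validation set (see [select_threshold()]).
#' @param n_boot Bootstrap resamples for metric CIs.
#' @param n_alert_cases Number of validation cases for the alert simulation.
#' @param overrides Nested list merged over everything above.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(n_cases = 60),
                       resample = resample_config(),
                       cleaning = cleaning_config(),
                       label = label_config(horizon = 5),
                       model = model_config(max_epochs = 20, eval_every = 5,
                                            patience = 2),
                       renal = renal_sim_config(n_patients = 4000),
                       spec = feature_spec(),
                       train_frac = 0.8,
                       threshold_strategy = "youden",
                       threshold_target = NULL,
                       n_boot = 200,
                       n_alert_cases = 10,
                       overrides = NULL) {
  cfg <- list(sim = sim, resample = resample, cleaning = cleaning,
              label = label, model = model, renal = renal, spec = spec,
              train_frac = train_frac,
              threshold_strategy = threshold_strategy,
              threshold_target = threshold_target,
              n_boot = n_boot, n_alert_cases = n_alert_cases)
  if (!is.null(overrides)) {
    cfg <- utils::modifyList(cfg, overrides, keep.null = TRUE)
  }
  structure(cfg, class = "run_config")
}

# Digest of the serialized config, embedded in every artifact.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(strip_classes(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

write_artifact <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

log_line <- function(out_dir, stage, ...) {
  if (is.null(out_dir)) return(invisible(NULL))
  rec <- c(list(stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(out_dir, "log.jsonl"), append = TRUE, sep = "")
}

#' Run the full synthetic IOH study end to end
#'
#' Orchestrates every stage under one root seed: cohort simulation,
#' 1-minute grid alignment, cleaning, patient-level splitting, epoch
#' dataset construction for the configured horizon, Transformer and
#' XGBoost training, validation evaluation (operating point, ROC/PR,
#' calibration), alert simulation on a random subset of validation cases,
#' and the nested burden -> AKI/AKD exposure analysis. With a fixed seed
#' the run is deterministic: artifacts written to `out_dir` are
#' byte-identical across reruns.
#'
#' @param config A [run_config()].
#' @param seed Root integer seed; every stage derives its own from it.
#' @param out_dir Optional output directory for JSON artifacts
#'   (`metrics.json`, `calibration.json`, `alerts.json`, `burden.json`,
#'   `config.json`, `log.jsonl`).
#' @param verbose Print stage progress.
#' @return A list with every intermediate and final result (invisible).
#' @export
run_pipeline <- function(config = run_config(), seed = 1L, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(msg) if (verbose) inform(msg)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  say("simulating cohort")
  cohort <- generate_cohort(config$sim, seed = child_seed(seed, 1))
  log_line(out_dir, "simulate", seed = child_seed(seed, 1),
           n_cases = nrow(cohort$cases))

  say("aligning to 1-min grid")
  gridded <- resample_to_grid(cohort$vitals, config$resample)

  say("splitting by patient")
  split <- split_by_patient(cohort$cases, train_frac = config$train_frac,
                            seed = child_seed(seed, 2))

  say("preprocessing")
  tr_raw <- filter(gridded, .data$case_id %in% split$train$case_id)
  va_raw <- filter(gridded, .data$case_id %in% split$validation$case_id)
  prep_tr <- preprocess_cohort(select(tr_raw, -any_of("patient_id")),
                               config$cleaning)
  prep_va <- preprocess_cohort(select(va_raw, -any_of("patient_id")),
                               config$cleaning, limits = prep_tr$limits)
  log_line(out_dir, "preprocess",
           excluded_train = nrow(prep_tr$report$excluded),
           excluded_val = nrow(prep_va$report$excluded))

  say("building datasets")
  ds_tr <- build_dataset(prep_tr$vitals, cohort$cases, config$label, config$spec)
  ds_va <- build_dataset(prep_va$vitals, cohort$cases, config$label, config$spec,
                         stats = ds_tr$stats)

  say("training transformer")
  tf <- train_transformer(NULL, ds_tr, ds_va, cfg = config$model,
                          seed = child_seed(seed, 3), verbose = verbose)
  say("training boosted benchmark")
  xgb <- train_boosted(ds_tr, seed = child_seed(seed, 4))

  say("evaluating")
  p_tf <- predict_proba(tf, ds_va)
  p_xgb <- predict_proba_boosted(xgb, ds_va)
  thr <- select_threshold(ds_va$y, p_tf, strategy = config$threshold_strategy,
                          target = config$threshold_target)
  thr_xgb <- select_threshold(ds_va$y, p_xgb,
                              strategy = config$threshold_strategy,
                              target = config$threshold_target)
  metrics <- bind_rows(
    mutate(metrics_report(ds_va$y, p_tf, thr, n_boot = config$n_boot,
                          seed = child_seed(seed, 5)),
           model = "transformer", .before = 1),
    mutate(metrics_report(ds_va$y, p_xgb, thr_xgb, n_boot = config$n_boot,
                          seed = child_seed(seed, 5)),
           model = "xgboost", .before = 1)
  )
  cal_tf <- ece(ds_va$y, p_tf, n_boot = config$n_boot,
                seed = child_seed(seed, 6))
  cal_xgb <- ece(ds_va$y, p_xgb, n_boot = config$n_boot,
                 seed = child_seed(seed, 6))

  say("simulating alerts")
  val_ids <- local_seed(child_seed(seed, 7), {
    ids <- unique(prep_va$vitals$case_id)
    sample(ids, min(config$n_alert_cases, length(ids)))
  })
  alert_vitals <- filter(prep_va$vitals, .data$case_id %in% val_ids)
  alerts <- alignment_report(tf, alert_vitals, cohort$cases, thr,
                             label_cfg = config$label)

  say("burden and renal outcomes")
  burden <- bind_rows(
    compute_burden(prep_tr$vitals, 65), compute_burden(prep_va$vitals, 65),
    compute_burden(prep_tr$vitals, 60), compute_burden(prep_va$vitals, 60),
    compute_burden(prep_tr$vitals, 55), compute_burden(prep_va$vitals, 55)
  )
  renal <- generate_renal_cohort(config$renal, seed = child_seed(seed, 8))
  staged <- stage_renal_outcomes(renal$creatinine,
                                 select(renal$cohort,
                                        all_of(c("patient_id", "baseline_scr"))))
  renal_tab <- left_join(select(renal$cohort, -all_of(c("aki", "aki_stage",
                                                        "akd", "akd_stage"))),
                         staged, by = "patient_id")
  fits <- purrr::map(c(aki = "aki", akd = "akd"), function(oc) {
    fit_burden_model(renal_tab, outcome = oc, burden_col = "burden_65",
                     threshold = 65)
  })
  transitions <- transition_table(renal_tab)

  if (!is.null(out_dir)) {
    write_artifact(list(horizon = config$label$horizon,
                        threshold = thr$threshold,
                        metrics = metrics), file.path(out_dir, "metrics.json"),
                   hash)
    write_artifact(list(transformer = glance(cal_tf), xgboost = glance(cal_xgb)),
                   file.path(out_dir, "calibration.json"), hash)
    write_artifact(list(summary = alerts$summary, per_case = alerts$per_case),
                   file.path(out_dir, "alerts.json"), hash)
    write_artifact(list(fits = purrr::map(fits, function(f) f$result),
                        transitions = transitions),
                   file.path(out_dir, "burden.json"), hash)
    write_artifact(list(seed = seed, config = strip_classes(config)),
                   file.path(out_dir, "config.json"), hash)
    log_line(out_dir, "done", hash = hash)
  }

  invisible(list(cohort = cohort, gridded = gridded, split = split,
                 prep_train = prep_tr, prep_val = prep_va,
                 ds_train = ds_tr, ds_val = ds_va,
                 transformer = tf, xgboost = xgb,
                 p_transformer = p_tf, p_xgboost = p_xgb,
                 threshold = thr, metrics = metrics,
                 calibration = list(transformer = cal_tf, xgboost = cal_xgb),
                 alerts = alerts, burden = burden,
                 renal = renal_tab, burden_fits = fits,
                 transitions = transitions, config = config, hash = hash))
}
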