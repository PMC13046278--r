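# A quickly trained tiny model over a small synthetic cohort, shared by the
# alerting tests.
alert_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- generate_cohort(sim_config(n_cases = 8, missing_rate = 0,
                                     spike_rate = 0, high_missing_frac = 0),
                          seed = 55)
    v <- dplyr::select(co$vitals, -patient_id)
    split <- split_by_patient(co$cases, seed = 2)
    cfg <- label_config(horizon = 5)
    tr <- build_dataset(dplyr::filter(v, case_id %in% split$train$case_id),
                        co$cases, cfg)
    va <- build_dataset(dplyr::filter(v, case_id %in% split$validation$case_id),
                        co$cases, cfg, stats = tr$stats)
    mcfg <- model_config(n_layers = 2, n_heads = 2, d_model = 16, d_ff = 32,
                         max_epochs = 2, eval_every = 1, patience = 2)
    fit <- train_transformer(NULL, tr, va, cfg = mcfg, seed = 5)
    cache <<- list(cohort = co, vitals = v, model = fit, label_cfg = cfg)
    cache
  }
})

test_that("rolling prediction yields one probability per eligible minute", {
  fx <- alert_fixture()
  one <- dplyr::filter(fx$vitals, case_id == fx$vitals$case_id[1])
  one30 <- one[one$time_min < 30, ]
  traj <- rolling_predict(fx$model, one30, fx$cohort$cases)
  expect_equal(nrow(traj), 30 - 15 + 1)   # minutes 14..29
  expect_equal(traj$t_end, 14:29)
  expect_true(all(traj$p >= 0 & traj$p <= 1))
  expect_equal(traj$map, one30$MAP[15:30])
  # repeat call identical
  traj2 <- rolling_predict(fx$model, one30, fx$cohort$cases)
  expect_identical(traj$p, traj2$p)
  # shorter than seq_len: empty with a warning
  expect_warning(short <- rolling_predict(fx$model, one[one$time_min < 10, ],
                                          fx$cohort$cases), "shorter")
  expect_equal(nrow(short), 0L)
})

test_that("rolling and batch predictions agree on identical epochs", {
  fx <- alert_fixture()
  one <- dplyr::filter(fx$vitals, case_id == fx$vitals$case_id[1])
  traj <- rolling_predict(fx$model, one, fx$cohort$cases)
  ds <- build_dataset(one, fx$cohort$cases, fx$label_cfg,
                      stats = fx$model$stats)
  p_batch <- predict_proba(fx$model, ds)
  common <- intersect(traj$t_end, ds$t_end)
  expect_gt(length(common), 10)
  expect_equal(traj$p[match(common, traj$t_end)],
               p_batch[match(common, ds$t_end)], tolerance = 1e-6)
})

test_that("alert simulation is monotone in the threshold and times leads", {
  # hand-built trajectory: full control over alerts
  traj <- tibble::tibble(case_id = "c1", t_end = 14:40,
                         p = c(rep(0.1, 10), 0.8, 0.9, rep(0.2, 15)),
                         map = 80)
  attr(traj, "horizon") <- 5L
  events <- tibble::tibble(case_id = "c1", start_min = 27L, end_min = 29L,
                           threshold = 65)
  al <- simulate_alerts(traj, 0.7, events, horizon = 5)
  expect_equal(nrow(al$alerts), 2L)                 # minutes 24, 25
  expect_equal(al$event_leads$lead_time, 27 - 24)   # first alert in window
  expect_true(al$event_leads$lead_time >= 1 && al$event_leads$lead_time <= 5)

  none <- simulate_alerts(traj, 0.95, events, horizon = 5)
  expect_equal(nrow(none$alerts), 0L)
  expect_true(is.na(none$event_leads$lead_time))

  all_al <- simulate_alerts(traj, 0, events, horizon = 5)
  expect_equal(nrow(all_al$alerts), nrow(traj))

  # raising the threshold never increases the alert count
  counts <- vapply(seq(0, 1, by = 0.05), function(th) {
    nrow(simulate_alerts(traj, th, events, horizon = 5)$alerts)
  }, double(1))
  expect_true(all(diff(counts) <= 0))

  # strict comparison and refractory suppression
  eq <- tibble::tibble(case_id = "c1", t_end = 14:18, p = rep(0.7, 5), map = 80)
  attr(eq, "horizon") <- 5L
  ev0 <- events[0, ]
  expect_equal(nrow(simulate_alerts(eq, 0.7, ev0, horizon = 5)$alerts), 5L)
  expect_equal(nrow(simulate_alerts(eq, 0.7, ev0, horizon = 5,
                                    strict = TRUE)$alerts), 0L)
  expect_equal(nrow(simulate_alerts(eq, 0.7, ev0, horizon = 5,
                                    refractory = 2)$alerts), 2L)
})

test_that("the cohort alignment report aggregates exactly", {
  fx <- alert_fixture()
  ids <- unique(fx$vitals$case_id)[1:4]
  v <- dplyr::filter(fx$vitals, case_id %in% ids)
  rep <- alignment_report(fx$model, v, fx$cohort$cases, threshold = 0.5,
                          label_cfg = fx$label_cfg)
  expect_equal(rep$summary$n_cases, 4)
  expect_equal(rep$summary$total_alerts, sum(rep$per_case$n_alerts))
  expect_equal(rep$summary$total_events, sum(rep$per_case$n_events))
  expect_equal(rep$summary$mean_events_per_case,
               rep$summary$total_events / 4)
  # per-case event counts match direct detection
  ev <- detect_ioh_events(v, fx$label_cfg)
  for (cid in ids) {
    expect_equal(rep$per_case$n_events[rep$per_case$case_id == cid],
                 sum(ev$case_id == cid))
  }
  # a zero-event cohort has no defined lead times
  calm <- make_simple_case(D = 60, case_id = ids[1], map = rep(85, 60))
  calm <- dplyr::mutate(calm, SBP = 120, DBP = 70)
  rep0 <- alignment_report(fx$model, calm, fx$cohort$cases, threshold = 0.5,
                           label_cfg = fx$label_cfg)
  expect_equal(rep0$summary$total_events, 0)
  expect_equal(nrow(rep0$event_leads), 0L)
})
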