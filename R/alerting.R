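# Rolling per-minute prediction over whole cases and alert simulation.

# Build an unlabeled epoch dataset covering every minute of each case that
# has a full seq_len history (no future window is required), using the
# model's frozen normalization statistics and feature spec.
rolling_dataset <- function(vitals, cases, model) {
  spec <- model$spec %||% feature_spec()
  cfg <- model$cfg
  L <- cfg$seq_len
  aug <- augment_dynamic_features(vitals, spec)
  aug <- select(aug, all_of(c("case_id", "time_min", spec$dynamic_channels)))
  z <- zscore_normalize(aug, stats = model$stats)
  zs <- split(z$vitals, z$vitals$case_id)
  blocks <- purrr::map(names(zs), function(cid) {
    zv <- arrange(zs[[cid]], .data$time_min)
    D <- nrow(zv)
    if (D < L) {
      warn(sprintf("case %s is shorter than seq_len (%d < %d): empty trajectory",
                   cid, D, L))
      return(NULL)
    }
    t_end <- (L - 1L):(D - 1L)
    M <- as.matrix(zv[, spec$dynamic_channels])
    M[is.na(M)] <- 0
    idx <- outer(t_end + 1L, (L - 1L):0L, "-")
    X <- array(NA_real_, c(length(t_end), L, length(spec$dynamic_channels)))
    for (f in seq_along(spec$dynamic_channels)) {
      X[, , f] <- matrix(M[idx, f], length(t_end), L)
    }
    list(case_id = cid, t_end = t_end, X = X)
  })
  blocks <- purrr::compact(blocks)
  if (!length(blocks)) {
    return(list(X_dyn = array(0, c(0, L, length(spec$dynamic_channels))),
                X_static = matrix(0, 0, length(spec$static)),
                y = integer(0), case_id = character(0), t_end = integer(0),
                seq_len = L, feature_names = spec$dynamic_channels,
                stats = model$stats, spec = spec, horizon = NA_integer_))
  }
  case_id <- unlist(purrr::map(blocks, function(b) rep(b$case_id, length(b$t_end))))
  t_end <- unlist(purrr::map(blocks, "t_end"))
  n <- length(t_end)
  X_dyn <- array(NA_real_, c(n, L, length(spec$dynamic_channels)))
  pos <- 0L
  for (b in blocks) {
    nb <- length(b$t_end)
    X_dyn[pos + seq_len(nb), , ] <- b$X
    pos <- pos + nb
  }
  cmatch <- match(case_id, cases$case_id)
  structure(list(X_dyn = X_dyn, X_static = encode_static(cases[cmatch, ], spec),
                 y = rep(0L, n), group = as.character(cases$patient_id[cmatch]),
                 case_id = case_id, t_end = as.integer(t_end), seq_len = L,
                 feature_names = spec$dynamic_channels, stats = model$stats,
                 spec = spec, horizon = NA_integer_),
            class = "epoch_dataset")
}

#' Rolling per-minute IOH risk prediction over whole cases
#'
#' Applies a trained model at every minute with a full `seq_len`-minute
#' history, mirroring real-time use: one probability per eligible minute,
#' deterministic (dropout off). A 30-min case with `seq_len` 15 yields 16
#' predictions (minutes 14-29). Cases shorter than `seq_len` yield an
#' empty trajectory with a warning.
#'
#' @param model A trained `ioh_transformer` (or `ioh_boosted`).
#' @param vitals Gridded, imputed wide tibble (physical units), one or more
#'   cases.
#' @param cases Case table with static covariates.
#' @param horizon Horizon annotation for the trajectory (defaults to the
#'   model's training horizon when known).
#' @return A tibble of class `prediction_trajectory`:
#'   `(case_id, t_end, p, map)` where `map` is the observed MAP at the
#'   epoch end-minute.
#' @export
rolling_predict <- function(model, vitals, cases, horizon = NULL) {
  ds <- rolling_dataset(vitals, cases, model)
  p <- if (inherits(model, "ioh_boosted")) {
    if (length(ds$y)) predict_proba_boosted(model, ds) else numeric(0)
  } else {
    predict_proba(model, ds)
  }
  mapv <- vitals |>
    select(all_of(c("case_id", "time_min", "MAP")))
  out <- tibble(case_id = ds$case_id, t_end = ds$t_end, p = p) |>
    left_join(mapv, by = c("case_id", "t_end" = "time_min")) |>
    rename(map = "MAP")
  attr(out, "horizon") <- horizon %||% model$horizon %||% NA_integer_
  class(out) <- c("prediction_trajectory", class(out))
  out
}

#' Simulate threshold alerts along a prediction trajectory
#'
#' An alert fires at every minute whose predicted probability reaches the
#' decision threshold (`>=` by default, matching the evaluation operating
#' point; set `strict = TRUE` for `>`). For each true IOH event the lead
#' time is the gap from the first qualifying alert within the preceding
#' `horizon`-minute window to the event start (1..horizon minutes, or `NA`
#' when no alert preceded the event). An optional refractory period
#' suppresses alerts within `refractory` minutes after one fires (off by
#' default). The per-event lead time is a package addition for synthetic
#' validation, not a statistic of the original alert simulation.
#'
#' @param trajectory A [rolling_predict()] trajectory (one or more cases).
#' @param threshold Decision threshold (or a `threshold_choice`).
#' @param events [detect_ioh_events()] table for the same cases.
#' @param horizon Horizon in minutes (defaults to the trajectory's).
#' @param strict Use strict `>` instead of `>=`.
#' @param refractory Minutes of alert suppression after each alert (0 = off).
#' @return A list of class `alert_summary`: `per_case` tibble
#'   `(case_id, n_alerts, n_events, mean_p, max_p)`, `event_leads` tibble
#'   `(case_id, start_min, lead_time)`, `alerts` tibble of alert minutes,
#'   and the threshold used.
#' @export
simulate_alerts <- function(trajectory, threshold, events, horizon = NULL,
                            strict = FALSE, refractory = 0) {
  if (inherits(threshold, "threshold_choice")) threshold <- threshold$threshold
  horizon <- horizon %||% attr(trajectory, "horizon")
  if (is.null(horizon) || is.na(horizon)) abort("`horizon` is required")
  fire <- if (strict) trajectory$p > threshold else trajectory$p >= threshold
  alerts <- trajectory[fire, c("case_id", "t_end", "p")]
  if (refractory > 0 && nrow(alerts)) {
    keep_rows <- alerts |>
      group_by(.data$case_id) |>
      dplyr::group_map(function(df, key) {
        keep <- logical(nrow(df))
        last <- -Inf
        for (i in seq_len(nrow(df))) {
          if (df$t_end[i] - last > refractory) {
            keep[i] <- TRUE
            last <- df$t_end[i]
          }
        }
        dplyr::bind_cols(key, df[keep, ])
      }) |>
      bind_rows()
    alerts <- keep_rows
  }
  per_case <- trajectory |>
    group_by(.data$case_id) |>
    summarise(mean_p = mean(.data$p), max_p = max(.data$p), .groups = "drop") |>
    left_join(count(alerts, .data$case_id, name = "n_alerts"), by = "case_id") |>
    left_join(count(events, .data$case_id, name = "n_events"), by = "case_id") |>
    mutate(n_alerts = dplyr::coalesce(.data$n_alerts, 0L),
           n_events = dplyr::coalesce(.data$n_events, 0L)) |>
    select(all_of(c("case_id", "n_alerts", "n_events", "mean_p", "max_p")))
  event_leads <- events |>
    filter(.data$case_id %in% unique(trajectory$case_id)) |>
    mutate(lead_time = purrr::map2_dbl(.data$case_id, .data$start_min,
      function(cid, s) {
        a <- alerts$t_end[alerts$case_id == cid &
                            alerts$t_end >= s - horizon & alerts$t_end < s]
        if (length(a)) s - min(a) else NA_real_
      })) |>
    select(all_of(c("case_id", "start_min", "lead_time")))
  structure(list(per_case = per_case, event_leads = event_leads,
                 alerts = alerts, threshold = threshold, horizon = horizon),
            class = "alert_summary")
}

#' Cohort-level alert alignment report
#'
#' Runs [rolling_predict()] and [simulate_alerts()] over a set of cases and
#' aggregates: total and mean alerts and true IOH events per case (the mean
#' is exactly total / n cases), mean/max predicted probability, and the
#' distribution of per-event lead times.
#'
#' @param model Trained model.
#' @param vitals Gridded, imputed wide tibble for the cases to report on.
#' @param cases Case table.
#' @param threshold Decision threshold.
#' @param label_cfg A [label_config()] for event detection.
#' @return A list of class `alignment_report`: `summary` one-row tibble,
#'   `per_case`, `event_leads`, and the underlying trajectory.
#' @export
alignment_report <- function(model, vitals, cases, threshold,
                             label_cfg = label_config()) {
  traj <- rolling_predict(model, vitals, cases, horizon = label_cfg$horizon)
  events <- detect_ioh_events(vitals, label_cfg)
  al <- simulate_alerts(traj, threshold, events, horizon = label_cfg$horizon)
  n_cases <- length(unique(vitals$case_id))
  summary <- tibble(
    n_cases = n_cases,
    total_alerts = sum(al$per_case$n_alerts),
    total_events = sum(al$per_case$n_events),
    mean_events_per_case = sum(al$per_case$n_events) / n_cases,
    mean_alerts_per_case = sum(al$per_case$n_alerts) / n_cases,
    mean_p = mean(traj$p),
    max_p = if (nrow(traj)) max(traj$p) else NA_real_,
    events_with_lead = sum(!is.na(al$event_leads$lead_time)),
    mean_lead_time = mean(al$event_leads$lead_time, na.rm = TRUE)
  )
  structure(list(summary = summary, per_case = al$per_case,
                 event_leads = al$event_leads, trajectory = traj,
                 threshold = al$threshold),
            class = "alignment_report")
}

#' @export
print.alert_summary <- function(x, ...) {
  cat(sprintf("<alert_summary> threshold %.3f, %d alert minute(s), %d event(s)\n",
              x$threshold, nrow(x$alerts), nrow(x$event_leads)))
  invisible(x)
}

#' @export
print.alignment_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<alignment_report> %d cases, %d events (mean %.1f/case), ",
                     "%d alerts, %d/%d events with a lead alert\n"),
              s$n_cases, s$total_events, s$mean_events_per_case,
              s$total_alerts, s$events_with_lead, s$total_events))
  invisible(x)
}
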