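#' Labeling configuration
#'
#' Defines an IOH event and the supervised epoch-labeling scheme. An event
#' is a maximal run of consecutive minutes with MAP strictly below
#' `threshold` lasting at least `min_duration` minutes; a missing MAP minute
#' breaks a run. The epoch ending at minute `t` is positive iff an event
#' *starts* within `(t, t + horizon]`, negative iff no minute in that window
#' is below threshold, and excluded otherwise (ambiguous: the window touches
#' an ongoing or sub-minimal run). With `exclude_in_event_epochs` (default),
#' epochs whose current minute is already hypotensive are dropped — alerting
#' on an event already underway is clinically vacuous.
#'
#' @param threshold MAP threshold in mmHg, one of 65 (default), 60, 55
#'   (other values allowed for exploration).
#' @param min_duration Minimum event duration in minutes (default 1).
#' @param horizon Prediction horizon in minutes, one of 5, 10, 15.
#' @param seq_len Input window length in timepoints (default 15).
#' @param exclude_in_event_epochs Drop epochs with MAP(t) < threshold.
#' @return A list of class `label_config`.
#' @export
label_config <- function(threshold = 65, min_duration = 1, horizon = 5,
                         seq_len = 15, exclude_in_event_epochs = TRUE) {
  stopifnot_scalar_number(threshold, "threshold", lower = 1)
  stopifnot_scalar_number(min_duration, "min_duration", lower = 1)
  stopifnot_scalar_number(horizon, "horizon", lower = 1)
  stopifnot_scalar_number(seq_len, "seq_len", lower = 1)
  structure(list(threshold = threshold, min_duration = as.integer(min_duration),
                 horizon = as.integer(horizon), seq_len = as.integer(seq_len),
                 exclude_in_event_epochs = isTRUE(exclude_in_event_epochs)),
            class = "label_config")
}

#' Detect intraoperative hypotension events
#'
#' Scans each case's gridded MAP channel for maximal runs of consecutive
#' minutes with MAP strictly below the threshold, keeping runs of at least
#' `min_duration` minutes. Missing MAP breaks a run. A case whose MAP is
#' entirely missing yields no events, with a warning.
#'
#' @param vitals Gridded wide tibble with a `MAP` column (one or more cases).
#' @param cfg A [label_config()].
#' @return Tibble `(case_id, start_min, end_min, threshold)`; `end_min` is
#'   inclusive.
#' @export
detect_ioh_events <- function(vitals, cfg = label_config()) {
  assert_vitals(vitals, "MAP")
  one <- function(df) {
    m <- df$MAP[order(df$time_min)]
    tt <- sort(df$time_min)
    if (all(is.na(m))) {
      warn(sprintf("case %s: MAP entirely missing, no events detectable", df$case_id[1]))
      return(tibble(case_id = character(), start_min = integer(),
                    end_min = integer(), threshold = double()))
    }
    below <- !is.na(m) & m < cfg$threshold
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= cfg$min_duration
    tibble(case_id = df$case_id[1],
           start_min = as.integer(tt[starts[keep]]),
           end_min = as.integer(tt[ends[keep]]),
           threshold = cfg$threshold)
  }
  vitals |>
    group_by(.data$case_id) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    bind_rows()
}

#' Label 1-minute epochs against a prediction horizon
#'
#' For every minute `t` with a full `seq_len`-minute history and a full
#' `horizon`-minute future inside the case, assigns: positive (1) if an IOH
#' event starts in `(t, t + horizon]`; negative (0) if no minute in that
#' window is below threshold; otherwise excluded (`NA` label with a reason).
#' Epochs with MAP(t) already below threshold are excluded when
#' `cfg$exclude_in_event_epochs`.
#'
#' @param vitals Gridded, imputed wide tibble.
#' @param cfg A [label_config()].
#' @param events Optional precomputed [detect_ioh_events()] table.
#' @return Tibble `(case_id, t_end, label, reason)`; `label` is 1/0/`NA` and
#'   `reason` is `"ok"`, `"in_event"` or `"ambiguous_window"`.
#' @export
label_epochs <- function(vitals, cfg = label_config(), events = NULL) {
  assert_vitals(vitals, "MAP")
  events <- events %||% detect_ioh_events(vitals, cfg)
  one <- function(df) {
    ord <- order(df$time_min)
    m <- df$MAP[ord]
    D <- length(m)
    lo <- cfg$seq_len - 1L            # 0-based first eligible end-minute
    hi <- D - 1L - cfg$horizon
    if (hi < lo) {
      return(tibble(case_id = character(), t_end = integer(),
                    label = integer(), reason = character()))
    }
    t_end <- lo:hi
    ev_start <- events$start_min[events$case_id == df$case_id[1]]
    below <- !is.na(m) & m < cfg$threshold
    # event start counts in windows (t, t+h]
    start_flag <- rep(FALSE, D)
    start_flag[ev_start + 1L] <- TRUE
    cs_start <- cumsum(start_flag)
    cs_below <- cumsum(below)
    n_start <- cs_start[t_end + 1L + cfg$horizon] - cs_start[t_end + 1L]
    n_below <- cs_below[t_end + 1L + cfg$horizon] - cs_below[t_end + 1L]
    label <- dplyr::case_when(n_start > 0L ~ 1L, n_below == 0L ~ 0L,
                              TRUE ~ NA_integer_)
    reason <- ifelse(is.na(label), "ambiguous_window", "ok")
    if (cfg$exclude_in_event_epochs) {
      in_ev <- below[t_end + 1L]
      label[in_ev] <- NA_integer_
      reason[in_ev] <- "in_event"
    }
    tibble(case_id = df$case_id[1], t_end = as.integer(t_end),
           label = label, reason = reason)
  }
  vitals |>
    group_by(.data$case_id) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    bind_rows()
}

#' Partition a cohort into training and validation folds by patient
#'
#' Patients — not cases — are randomly assigned, so every case of a patient
#' lands in one fold and no patient straddles the split. Patients are
#' shuffled under the seed and accumulated into the training fold until the
#' case count is nearest the target fraction, which keeps the achieved case
#' fraction within a fraction of a percent of `train_frac` on cohorts of
#' hundreds of patients.
#'
#' @param cases Tibble with `case_id` and `patient_id` columns (one row per
#'   case).
#' @param train_frac Target fraction of cases in the training fold.
#' @param seed Integer seed.
#' @return `list(train, validation)` of `cases` subsets.
#' @export
split_by_patient <- function(cases, train_frac = 0.8, seed = 1L) {
  if (!all(c("case_id", "patient_id") %in% names(cases))) {
    abort("`cases` must have case_id and patient_id columns")
  }
  pats <- unique(cases$patient_id)
  if (length(pats) < 2L) abort("cannot split: need at least 2 patients")
  local_seed(seed, {
    pats <- sample(pats)
  })
  n_cases_per <- vapply(pats, function(p) sum(cases$patient_id == p), integer(1))
  cum <- cumsum(n_cases_per)
  target <- train_frac * nrow(cases)
  k <- which.min(abs(cum - target))
  train_p <- pats[seq_len(k)]
  list(train = filter(cases, .data$patient_id %in% train_p),
       validation = filter(cases, !.data$patient_id %in% train_p))
}
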