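#' Cleaning configuration
#'
#' Parameters of the cleaning pipeline: per-channel physiological
#' plausibility bounds (values strictly outside the bounds are removed, so a
#' MAP of exactly 30 mmHg is retained), the percentile pair used for outlier
#' truncation, the case-exclusion missingness cap, and the formula used to
#' impute MAP from systolic/diastolic pressure.
#'
#' The four printed bounds are MAP \[30,200\] mmHg, HR \[25,220\] bpm,
#' SpO2 \[50,100\] %, ETCO2 \[5,80\] mmHg; the remaining channels carry
#' package defaults and all are overridable via `bounds`.
#'
#' `map_formula = "standard"` uses MAP = DBP + (SBP - DBP)/3, the
#' physiological mean-pressure approximation. `"as_printed"` uses
#' MAP = 1/3 DBP + 2/3 SBP, which inverts the conventional weights; it is
#' retained verbatim as a selectable variant rather than silently corrected.
#'
#' @param bounds Named list of `c(lower, upper)` per channel, merged over the
#'   defaults.
#' @param trunc_percentiles Lower/upper truncation percentiles (default
#'   0.1 and 99.9).
#' @param max_missing_fraction Cases with a missing-cell fraction strictly
#'   above this (over channels x minutes, after plausibility filtering and
#'   before imputation) are excluded. Default 0.10.
#' @param map_formula `"standard"` or `"as_printed"`.
#' @param min_points_for_truncation Channels with fewer pooled non-missing
#'   points skip truncation with a warning (default 1000).
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(bounds = list(),
                            trunc_percentiles = c(0.1, 99.9),
                            max_missing_fraction = 0.10,
                            map_formula = c("standard", "as_printed"),
                            min_points_for_truncation = 1000) {
  defaults <- list(
    MAP = c(30, 200), HR = c(25, 220), SPO2 = c(50, 100), ETCO2 = c(5, 80),
    PULSE = c(25, 220), SBP = c(40, 300), DBP = c(15, 225),
    NIBP_SYS = c(40, 300), NIBP_DIA = c(15, 225), RR = c(2, 60), TEMP = c(30, 43)
  )
  defaults[names(bounds)] <- bounds
  for (ch in names(defaults)) {
    b <- defaults[[ch]]
    if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2]) {
      abort(sprintf("bounds for %s must be c(lower, upper) with lower < upper", ch))
    }
  }
  if (length(trunc_percentiles) != 2L || any(trunc_percentiles < 0) ||
      any(trunc_percentiles > 100) || trunc_percentiles[1] >= trunc_percentiles[2]) {
    abort("`trunc_percentiles` must be two increasing values in [0, 100]")
  }
  stopifnot_scalar_number(max_missing_fraction, "max_missing_fraction",
                          lower = 1e-12, upper = 1 - 1e-12)
  structure(list(
    bounds = defaults,
    trunc_percentiles = trunc_percentiles,
    max_missing_fraction = max_missing_fraction,
    map_formula = match.arg(map_formula),
    min_points_for_truncation = min_points_for_truncation
  ), class = "cleaning_config")
}

new_cleaning_report <- function(channels, excluded = NULL, n_cells = NA_real_) {
  structure(list(
    channels = channels,
    excluded = excluded %||% tibble(case_id = character(), missing_fraction = double(),
                                    reason = character()),
    n_cells = n_cells
  ), class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  print(x$channels)
  if (nrow(x$excluded)) {
    cat("excluded cases:\n")
    print(x$excluded)
  }
  if (is.finite(x$n_cells)) {
    aff <- sum(x$channels$n_implausible, x$channels$n_truncated, na.rm = TRUE)
    cat(sprintf("fraction of cells removed or truncated: %.4g\n", aff / x$n_cells))
  }
  invisible(x)
}

#' Remove physiologically implausible values
#'
#' Values strictly outside the per-channel plausibility bounds are replaced
#' by the missing marker (`NA`); boundary values are retained. Channels
#' without configured bounds pass through unchanged.
#'
#' @param vitals Gridded wide tibble.
#' @param cfg A [cleaning_config()].
#' @return `list(vitals, report)` where `report` is a [cleaning_config()]
#'   per-channel count table of class `cleaning_report`.
#' @export
apply_plausibility_filter <- function(vitals, cfg = cleaning_config()) {
  assert_vitals(vitals)
  chans <- channel_cols(vitals)
  counts <- tibble(channel = chans, n_implausible = 0L)
  for (i in seq_along(chans)) {
    ch <- chans[i]
    b <- cfg$bounds[[ch]]
    if (is.null(b)) next
    v <- vitals[[ch]]
    bad <- !is.na(v) & (v < b[1] | v > b[2])
    counts$n_implausible[i] <- sum(bad)
    if (any(bad)) vitals[[ch]][bad] <- NA_real_
  }
  list(vitals = vitals,
       report = new_cleaning_report(counts, n_cells = nrow(vitals) * length(chans)))
}

#' Truncate statistical outliers to cohort percentile limits
#'
#' Percentile limits (default 0.1st and 99.9th, type-7 definition) are
#' estimated per channel over the pooled training cohort and values beyond
#' them are clamped to the limit. The limits are returned so they can be
#' reused verbatim on validation or external data. Channels with fewer than
#' `cfg$min_points_for_truncation` pooled points skip truncation with a
#' warning.
#'
#' @param vitals Gridded wide tibble (the cohort the limits are estimated on,
#'   or any cohort when `limits` is supplied).
#' @param cfg A [cleaning_config()].
#' @param limits Optional tibble `(channel, lower, upper)` of frozen limits.
#' @return `list(vitals, report, limits)`.
#' @export
truncate_outliers <- function(vitals, cfg = cleaning_config(), limits = NULL) {
  assert_vitals(vitals)
  chans <- channel_cols(vitals)
  if (is.null(limits)) {
    limits <- purrr::map_dfr(chans, function(ch) {
      v <- vitals[[ch]]
      n <- sum(!is.na(v))
      if (n < cfg$min_points_for_truncation) {
        warn(sprintf("channel %s has %d pooled points (< %d): truncation skipped",
                     ch, n, cfg$min_points_for_truncation))
        return(tibble(channel = ch, lower = NA_real_, upper = NA_real_))
      }
      tibble(channel = ch,
             lower = pctl(v, cfg$trunc_percentiles[1]),
             upper = pctl(v, cfg$trunc_percentiles[2]))
    })
  }
  counts <- tibble(channel = chans, n_truncated = 0L)
  for (i in seq_along(chans)) {
    ch <- chans[i]
    lim <- limits[limits$channel == ch, ]
    if (nrow(lim) == 0L || is.na(lim$lower)) next
    v <- vitals[[ch]]
    bad <- !is.na(v) & (v < lim$lower | v > lim$upper)
    counts$n_truncated[i] <- sum(bad)
    vitals[[ch]] <- pmin(pmax(v, lim$lower), lim$upper)
  }
  list(vitals = vitals,
       report = new_cleaning_report(counts, n_cells = nrow(vitals) * length(chans)),
       limits = limits)
}

#' Impute missing MAP from systolic and diastolic pressure
#'
#' Fills missing MAP at timepoints where both SBP and DBP are present, using
#' the formula selected in `cfg$map_formula` (see [cleaning_config()]).
#' Timepoints with SBP < DBP are left unimputed and reported.
#'
#' @inheritParams apply_plausibility_filter
#' @return `list(vitals, report)`; `report$channels` carries the imputed
#'   count for MAP and the number of skipped inconsistent timepoints.
#' @export
impute_map <- function(vitals, cfg = cleaning_config()) {
  assert_vitals(vitals, c("MAP"))
  has_bp <- all(c("SBP", "DBP") %in% names(vitals))
  n_imp <- 0L; n_skip <- 0L
  if (has_bp) {
    sbp <- vitals$SBP; dbp <- vitals$DBP
    idx <- which(is.na(vitals$MAP) & !is.na(sbp) & !is.na(dbp))
    bad <- idx[sbp[idx] < dbp[idx]]
    if (length(bad)) {
      n_skip <- length(bad)
      inform(sprintf("%d timepoint(s) with SBP < DBP: MAP not imputed there", n_skip))
      idx <- setdiff(idx, bad)
    }
    n_imp <- length(idx)
    if (n_imp) {
      vitals$MAP[idx] <- if (cfg$map_formula == "standard") {
        dbp[idx] + (sbp[idx] - dbp[idx]) / 3
      } else {
        dbp[idx] / 3 + 2 * sbp[idx] / 3
      }
    }
  }
  rep <- tibble(channel = "MAP", n_imputed_formula = n_imp, n_skipped_sbp_lt_dbp = n_skip)
  list(vitals = vitals, report = new_cleaning_report(rep))
}

ffill_vec <- function(v) {
  ob <- which(!is.na(v))
  if (!length(ob)) return(v)
  idx <- findInterval(seq_along(v), ob)
  out <- v[ob][pmax(idx, 1L)]
  out[idx == 0L] <- NA_real_
  out
}

#' Forward-fill remaining gaps within each case
#'
#' Applied after formula imputation: every channel's remaining gaps are
#' filled with the last observed value within the same case. Leading gaps
#' (before a channel's first observation) stay missing — there is no
#' backward fill.
#'
#' @param vitals Gridded wide tibble.
#' @return `list(vitals, report)` with per-channel filled-cell counts.
#' @export
forward_fill_impute <- function(vitals) {
  assert_vitals(vitals)
  chans <- channel_cols(vitals)
  before <- vapply(chans, function(ch) sum(is.na(vitals[[ch]])), integer(1))
  vitals <- vitals |>
    group_by(.data$case_id) |>
    mutate(across(all_of(chans), ffill_vec)) |>
    ungroup()
  after <- vapply(chans, function(ch) sum(is.na(vitals[[ch]])), integer(1))
  rep <- tibble(channel = chans, n_imputed_ffill = as.integer(before - after))
  list(vitals = vitals, report = new_cleaning_report(rep))
}

#' Per-case missing-data fraction
#'
#' Fraction of missing cells over all channels x minutes for each case.
#' @param vitals Gridded wide tibble.
#' @return Tibble `(case_id, missing_fraction)`.
#' @export
missing_fraction <- function(vitals) {
  assert_vitals(vitals)
  chans <- channel_cols(vitals)
  vitals |>
    group_by(.data$case_id) |>
    summarise(missing_fraction =
                sum(is.na(dplyr::pick(all_of(chans)))) / (n() * length(chans)),
              .groups = "drop")
}

#' Exclude cases with excessive missing vital-sign data
#'
#' A case is excluded iff its overall missing fraction — missing cells over
#' channels x minutes, measured after plausibility filtering and before
#' imputation — strictly exceeds `cfg$max_missing_fraction` (a case at
#' exactly the cap is kept).
#'
#' @param vitals Gridded wide tibble.
#' @param cfg A [cleaning_config()].
#' @param fractions Optional precomputed [missing_fraction()] table (used by
#'   the pipeline, which measures missingness before imputation but applies
#'   the exclusion afterwards).
#' @return `list(kept, excluded, report)`: the two vitals subsets and a
#'   `cleaning_report` listing excluded cases.
#' @export
exclude_high_missingness <- function(vitals, cfg = cleaning_config(),
                                     fractions = NULL) {
  assert_vitals(vitals)
  fr <- fractions %||% missing_fraction(vitals)
  drop_ids <- fr$case_id[fr$missing_fraction > cfg$max_missing_fraction]
  excl <- fr |>
    filter(.data$case_id %in% drop_ids) |>
    mutate(reason = sprintf("missing fraction %.3f > %.2f",
                            .data$missing_fraction, cfg$max_missing_fraction))
  list(kept = filter(vitals, !.data$case_id %in% drop_ids),
       excluded = filter(vitals, .data$case_id %in% drop_ids),
       report = new_cleaning_report(tibble(channel = character()),
                                    excluded = excl))
}

#' Z-score normalization with frozen training statistics
#'
#' Normalizes every channel to `(x - mu) / sigma`. When `stats` is `NULL` the
#' statistics are estimated from `vitals` (the training cohort) and returned
#' for verbatim reuse on validation or external data. A constant channel
#' (sigma = 0) maps to 0 with a warning. Applying saved statistics twice is
#' not the same as applying them once: the transform is affine, not
#' idempotent.
#'
#' @param vitals Gridded wide tibble.
#' @param stats Optional tibble `(channel, mu, sigma)` of frozen statistics.
#' @return `list(vitals, stats)`.
#' @export
zscore_normalize <- function(vitals, stats = NULL) {
  assert_vitals(vitals)
  chans <- channel_cols(vitals)
  if (is.null(stats)) {
    stats <- purrr::map_dfr(chans, function(ch) {
      v <- vitals[[ch]]
      tibble(channel = ch, mu = mean(v, na.rm = TRUE),
             sigma = sd(v, na.rm = TRUE))
    })
    stats$mu[is.nan(stats$mu)] <- 0
    stats$sigma[is.na(stats$sigma)] <- 0
  }
  for (i in seq_len(nrow(stats))) {
    ch <- stats$channel[i]
    if (!ch %in% names(vitals)) next
    if (stats$sigma[i] == 0) {
      warn(sprintf("channel %s has zero variance: normalized to 0", ch))
      vitals[[ch]] <- ifelse(is.na(vitals[[ch]]), NA_real_, 0)
    } else {
      vitals[[ch]] <- (vitals[[ch]] - stats$mu[i]) / stats$sigma[i]
    }
  }
  list(vitals = vitals, stats = stats)
}

merge_reports <- function(...) {
  reps <- list(...)
  tabs <- purrr::map(reps, "channels")
  channels <- purrr::reduce(tabs, function(a, b) {
    dplyr::full_join(a, b, by = "channel")
  })
  for (col in setdiff(names(channels), "channel")) {
    channels[[col]][is.na(channels[[col]])] <- 0L
  }
  excl <- bind_rows(purrr::map(reps, "excluded"))
  n_cells <- purrr::detect(purrr::map(reps, "n_cells"), is.finite) %||% NA_real_
  new_cleaning_report(channels, excluded = excl, n_cells = n_cells)
}

#' Run the full cleaning pipeline on a cohort
#'
#' Fixed order: plausibility filter -> percentile truncation -> missingness
#' measurement -> MAP formula imputation -> forward fill -> case exclusion.
#' Truncation limits are estimated on this cohort when `limits` is `NULL`
#' (training) and reused verbatim otherwise (validation/external). With
#' frozen limits the pipeline is idempotent end to end. Normalization is
#' separate ([zscore_normalize()]) because burden computation and feature
#' derivation need physical units.
#'
#' @param vitals Gridded wide tibble.
#' @param cfg A [cleaning_config()].
#' @param limits Optional frozen truncation limits.
#' @return `list(vitals, excluded, report, limits)`; `vitals` is cleaned and
#'   imputed, in physical units.
#' @export
preprocess_cohort <- function(vitals, cfg = cleaning_config(), limits = NULL) {
  s1 <- apply_plausibility_filter(vitals, cfg)
  s2 <- truncate_outliers(s1$vitals, cfg, limits = limits)
  fr <- missing_fraction(s2$vitals)
  s3 <- impute_map(s2$vitals, cfg)
  s4 <- forward_fill_impute(s3$vitals)
  s5 <- exclude_high_missingness(s4$vitals, cfg, fractions = fr)
  list(vitals = s5$kept,
       excluded = s5$excluded,
       report = merge_reports(s1$report, s2$report, s3$report, s4$report, s5$report),
       limits = s2$limits)
}
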