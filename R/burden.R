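#' Hypotension burden (area under threshold) per case
#'
#' Cumulative exposure to MAP at or below a threshold. `mode = "area"`
#' (default) is the depth-weighted area under the threshold,
#' `sum over minutes of max(0, threshold - MAP) x 1 min` (mmHg.min), for
#' minutes with MAP <= threshold; `mode = "duration"` reports the minutes
#' below threshold instead. The exposure comparison is `<=` (a minute at
#' exactly the threshold counts toward duration but contributes zero area),
#' intentionally different from event *detection*, which uses strict `<`.
#' Missing minutes contribute 0 and are counted; a case with entirely
#' missing MAP is an error.
#'
#' @param vitals Gridded, imputed wide tibble with `MAP` (one or more cases).
#' @param threshold MAP threshold in mmHg (65, 60 or 55 in the study).
#' @param mode `"area"` or `"duration"`.
#' @return Tibble `(case_id, threshold, mode, area, minutes_below,
#'   n_missing)`; both the area and the duration are always reported, `mode`
#'   records which one is the exposure of interest.
#' @export
compute_burden <- function(vitals, threshold = 65, mode = c("area", "duration")) {
  mode <- match.arg(mode)
  assert_vitals(vitals, "MAP")
  out <- vitals |>
    group_by(.data$case_id) |>
    summarise(
      threshold = threshold,
      mode = mode,
      area = sum(pmax(0, threshold - .data$MAP)[.data$MAP <= threshold],
                 na.rm = TRUE),
      minutes_below = sum(.data$MAP <= threshold, na.rm = TRUE),
      n_missing = sum(is.na(.data$MAP)),
      n_total = n(),
      .groups = "drop"
    )
  bad <- out$case_id[out$n_missing == out$n_total]
  if (length(bad)) {
    abort(paste0("MAP entirely missing, burden undefined for case(s): ",
                 paste(bad, collapse = ", ")))
  }
  select(out, -"n_total")
}

# Shared KDIGO-style creatinine-ratio staging.
stage_from_ratio <- function(ratio) {
  if (ratio >= 3) 3L else if (ratio >= 2) 2L else if (ratio >= 1.5) 1L else 0L
}

#' KDIGO creatinine staging of acute kidney injury (days 0-7)
#'
#' Serum-creatinine criteria only (urine output is out of scope): stage >= 1
#' if creatinine rises >= 0.3 mg/dL within any 48-h window (the baseline
#' counts as a day-0 value) or reaches >= 1.5x baseline within 7 days;
#' stage 2 at >= 2.0x; stage 3 at >= 3.0x or an absolute value >= 4.0 mg/dL
#' accompanied by a qualifying rise. A patient with no postoperative value
#' within 7 days is indeterminate (`NA`), mirroring the cohort restriction
#' to patients with at least one pre- and postoperative measurement.
#'
#' @param timeline Tibble `(postop_day, scr_mg_dl)` for one patient;
#'   `postop_day` > 0.
#' @param baseline Preoperative creatinine (mg/dL).
#' @return Integer stage 0-3, or `NA` if indeterminate.
#' @export
stage_aki_kdigo <- function(timeline, baseline) {
  stopifnot_scalar_number(baseline, "baseline", lower = 1e-6)
  tl <- filter(timeline, .data$postop_day > 0, .data$postop_day <= 7,
               !is.na(.data$scr_mg_dl))
  if (nrow(tl) == 0L) return(NA_integer_)
  pts <- bind_rows(tibble(postop_day = 0, scr_mg_dl = baseline),
                   tl[order(tl$postop_day), ])
  rise48 <- FALSE
  for (j in 2:nrow(pts)) {
    prior <- pts$postop_day[j] - pts$postop_day < 2 + 1e-9 &
      pts$postop_day < pts$postop_day[j] + 1e-9
    if (any(pts$scr_mg_dl[j] - pts$scr_mg_dl[prior] >= 0.3 - 1e-12)) {
      rise48 <- TRUE
      break
    }
  }
  ratio <- max(tl$scr_mg_dl) / baseline
  st <- stage_from_ratio(ratio)
  if (st == 0L && rise48) st <- 1L
  if (st >= 1L && max(tl$scr_mg_dl) >= 4.0) st <- 3L
  st
}

#' ADQI creatinine staging of acute kidney disease (days 8-90)
#'
#' KDIGO-style creatinine-ratio staging applied to values between 8 and 90
#' days after surgery: stage 1 at >= 1.5x baseline, 2 at >= 2.0x, 3 at
#' >= 3.0x; stage 0 when no qualifying value exists in the window (full
#' recovery by day 8 is stage 0).
#'
#' @inheritParams stage_aki_kdigo
#' @return Integer stage 0-3.
#' @export
stage_akd <- function(timeline, baseline) {
  stopifnot_scalar_number(baseline, "baseline", lower = 1e-6)
  tl <- filter(timeline, .data$postop_day >= 8, .data$postop_day <= 90,
               !is.na(.data$scr_mg_dl))
  if (nrow(tl) == 0L) return(0L)
  stage_from_ratio(max(tl$scr_mg_dl) / baseline)
}

#' Stage renal outcomes for a whole cohort
#'
#' Vectorized wrapper applying [stage_aki_kdigo()] and [stage_akd()] per
#' patient.
#'
#' @param creatinine Long tibble `(patient_id, postop_day, scr_mg_dl)`.
#' @param baselines Tibble `(patient_id, baseline_scr)`.
#' @return Tibble `(patient_id, aki_stage, akd_stage, aki, akd)`; `aki`/
#'   `akd` are the stage >= 1 flags.
#' @export
stage_renal_outcomes <- function(creatinine, baselines) {
  tls <- split(creatinine, creatinine$patient_id)
  purrr::map_dfr(seq_len(nrow(baselines)), function(i) {
    pid <- baselines$patient_id[i]
    tl <- tls[[pid]] %||% tibble(postop_day = double(), scr_mg_dl = double())
    aki <- stage_aki_kdigo(tl, baselines$baseline_scr[i])
    akd <- stage_akd(tl, baselines$baseline_scr[i])
    tibble(patient_id = pid, aki_stage = aki, akd_stage = akd,
           aki = as.integer(aki >= 1L), akd = as.integer(akd >= 1L))
  })
}

#' Logistic exposure-outcome model for hypotension burden
#'
#' Multivariable logistic regression of a renal outcome on hypotension
#' burden scaled to `scale` mmHg.min increments (default 60, so the odds
#' ratio is per 60 mmHg.min of exposure), adjusted for the listed
#' covariates. Wald 95% CI and p-value. Errors on zero outcome events and
#' on detected separation.
#'
#' @param cohort Tibble with the outcome column, a burden column and the
#'   covariates.
#' @param outcome Outcome column name (`"aki"` or `"akd"`).
#' @param burden_col Burden column name (mmHg.min), e.g. `"burden_65"`.
#' @param covariates Character vector of adjustment covariate columns.
#' @param threshold MAP threshold the burden column was computed at
#'   (annotation only).
#' @param scale Exposure scaling constant in mmHg.min (default 60).
#' @return A list of class `burden_fit`: the `glm` fit and a one-row
#'   `result` tibble `(threshold, outcome, or, ci_lo, ci_hi, p_value, n,
#'   events, scale)`.
#' @export
fit_burden_model <- function(cohort, outcome = "aki", burden_col = "burden_65",
                             covariates = c("age", "sex", "diabetes",
                                            "duration_min"),
                             threshold = 65, scale = 60) {
  need <- c(outcome, burden_col, covariates)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  y <- cohort[[outcome]]
  keep <- !is.na(y)
  cohort <- cohort[keep, ]
  y <- y[keep]
  if (sum(y) == 0L) abort("zero outcome events: odds ratio undefined")
  if (sum(y) == length(y)) abort("all observations are events: odds ratio undefined")
  df <- cohort[, covariates, drop = FALSE]
  df$.exposure <- cohort[[burden_col]] / scale
  if (all(df$.exposure == 0)) {
    abort("exposure is zero for every observation: odds ratio undefined")
  }
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~ .exposure +",
                                 paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  if (!fit$converged) abort("logistic model did not converge")
  co <- summary(fit)$coefficients
  b <- co[".exposure", "Estimate"]
  se <- co[".exposure", "Std. Error"]
  if (abs(b) > 15 || se > 15) {
    abort(sprintf(paste0("separation suspected: exposure coefficient %.2f ",
                         "(SE %.2f); check the exposure distribution"), b, se))
  }
  res <- tibble(
    threshold = threshold, outcome = outcome,
    or = exp(b), ci_lo = exp(b - qnorm(0.975) * se),
    ci_hi = exp(b + qnorm(0.975) * se),
    p_value = co[".exposure", "Pr(>|z|)"],
    n = length(y), events = sum(y), scale = scale
  )
  structure(list(fit = fit, result = res, covariates = covariates,
                 burden_col = burden_col),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<burden_fit> %s ~ burden (MAP <=%g): OR %.3f (%.3f, %.3f) per %g mmHg.min, p = %.3g (n = %d, events = %d)\n",
    r$outcome, r$threshold, r$or, r$ci_lo, r$ci_hi, r$scale, r$p_value,
    r$n, r$events))
  invisible(x)
}

#' @export
tidy.burden_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co),
         estimate = co[, "Estimate"],
         std_error = co[, "Std. Error"],
         statistic = co[, "z value"],
         p_value = co[, "Pr(>|z|)"],
         odds_ratio = exp(co[, "Estimate"]))
}

#' @export
glance.burden_fit <- function(x, ...) x$result

#' AKI-stage by AKD-stage transition table
#'
#' Contingency counts of the progression from acute kidney injury (days
#' 0-7) to acute kidney disease (days 8-90), the quantity behind a Sankey
#' diagram of renal-injury trajectories.
#'
#' @param outcomes Tibble with `aki_stage` and `akd_stage` (0-3;
#'   indeterminate AKI rows are dropped).
#' @return Tibble `(aki_stage, akd_stage, n)` complete over the 4 x 4 grid.
#' @export
transition_table <- function(outcomes) {
  outcomes |>
    filter(!is.na(.data$aki_stage)) |>
    count(.data$aki_stage, .data$akd_stage) |>
    tidyr::complete(aki_stage = 0:3, akd_stage = 0:3, fill = list(n = 0L))
}
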