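#' Feature specification for both model families
#'
#' The dynamic input comprises the 11 monitored channels plus 6 MAP-derived
#' trend channels (17 dynamic features), and 2 static covariates (age, sex).
#' The derived channels capture the pre-hypotensive drift that precedes an
#' event: 1- and 5-minute MAP differences, trailing 5-minute rolling mean,
#' standard deviation and minimum, and the count of minutes below 70 mmHg in
#' the trailing 5-minute window (70 mmHg sits above the 65 mmHg event
#' threshold, so this feature activates before an event does).
#'
#' For the gradient-boosted benchmark each window is flattened into 7
#' summary statistics per base channel — mean, sd, min, max, last value,
#' first-difference slope, and minutes below a channel-specific reference
#' (70 mmHg for MAP, 90% for SpO2, ...) — plus the static covariates.
#'
#' @param base_channels Monitored channels used as dynamic inputs.
#' @param derived Names of the MAP-derived trend channels to append.
#' @param static Static covariate names (columns of the case table).
#' @param below_ref Named numeric vector of per-channel references for the
#'   minutes-below summary statistic.
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(base_channels = ioh_channels(),
                         derived = c("MAP_D1", "MAP_D5", "MAP_RM5",
                                     "MAP_RSD5", "MAP_RMIN5", "MAP_TB70"),
                         static = c("age", "sex"),
                         below_ref = c(HR = 50, PULSE = 50, SBP = 90, DBP = 50,
                                       MAP = 70, NIBP_SYS = 90, NIBP_DIA = 50,
                                       RR = 8, SPO2 = 90, ETCO2 = 30, TEMP = 36)) {
  structure(list(base_channels = base_channels, derived = derived,
                 static = static, below_ref = below_ref,
                 dynamic_channels = c(base_channels, derived)),
            class = "feature_spec")
}

roll_stat <- function(v, w, fun) {
  n <- length(v)
  vapply(seq_len(n), function(i) fun(v[max(1L, i - w + 1L):i]), double(1))
}

#' Append MAP-derived trend channels
#'
#' Computes the derived channels of [feature_spec()] per case on the imputed
#' MAP channel, in physical units. Trailing windows are truncated at the
#' case start; differences are 0 at minutes without a full lag.
#'
#' @param vitals Gridded, imputed wide tibble with `MAP`.
#' @param spec A [feature_spec()].
#' @return `vitals` with the derived columns appended.
#' @export
augment_dynamic_features <- function(vitals, spec = feature_spec()) {
  assert_vitals(vitals, "MAP")
  if (!length(spec$derived)) return(vitals)
  one <- function(df) {
    df <- arrange(df, .data$time_min)
    m <- df$MAP
    lag_diff <- function(k) {
      d <- m - dplyr::lag(m, k)
      d[is.na(d)] <- 0
      d
    }
    add <- list(
      MAP_D1 = lag_diff(1L),
      MAP_D5 = lag_diff(5L),
      MAP_RM5 = roll_stat(m, 5L, function(x) mean(x, na.rm = TRUE)),
      MAP_RSD5 = roll_stat(m, 5L, function(x) {
        s <- sd(x, na.rm = TRUE); if (is.na(s)) 0 else s
      }),
      MAP_RMIN5 = roll_stat(m, 5L, function(x) {
        if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
      }),
      MAP_TB70 = roll_stat(m, 5L, function(x) sum(!is.na(x) & x < 70))
    )
    for (ch in intersect(spec$derived, names(add))) df[[ch]] <- add[[ch]]
    df
  }
  vitals |>
    group_by(.data$case_id) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    bind_rows()
}

# Fixed affine coding of the static covariates: age in years centered at 50
# and scaled by 15; sex in {0,1} centered. Constant, hence leakage-free.
encode_static <- function(cases, spec) {
  out <- matrix(0, nrow(cases), length(spec$static),
                dimnames = list(NULL, spec$static))
  for (s in spec$static) {
    v <- cases[[s]]
    if (is.null(v)) abort(sprintf("static covariate '%s' missing from case table", s))
    if (s == "age") v <- (as.numeric(v) - 50) / 15
    if (s == "sex") v <- as.numeric(v) - 0.5
    out[, s] <- as.numeric(v)
  }
  out
}

#' Flatten epoch windows into summary features for tree-based learning
#'
#' Maps every epoch window of an [build_dataset()] dataset to the per-channel
#' summary statistics of [feature_spec()] (7 per base channel) plus the
#' static covariates. Windows stored normalized are converted back to
#' physical units with the dataset's frozen statistics, so thresholds such
#' as "minutes below 70 mmHg" keep their literal meaning. Feature names are
#' stable (`<channel>_<stat>`).
#'
#' @param dataset An `epoch_dataset` from [build_dataset()].
#' @param spec A [feature_spec()] (defaults to the dataset's own).
#' @return Numeric matrix `n x (7 |channels| + |static|)` with column names.
#' @export
derive_features <- function(dataset, spec = NULL) {
  spec <- spec %||% dataset$spec
  stats <- dataset$stats
  chans <- spec$base_channels
  stat_names <- c("mean", "sd", "min", "max", "last", "slope", "below_ref")
  L <- dataset$seq_len
  n <- length(dataset$y)
  out <- matrix(NA_real_, n, length(chans) * length(stat_names) + length(spec$static))
  colnames(out) <- c(as.vector(t(outer(chans, stat_names, paste, sep = "_"))),
                     spec$static)
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    f <- match(ch, dataset$feature_names)
    if (is.na(f)) abort(sprintf("channel %s not in dataset features", ch))
    W <- dataset$X_dyn[, , f, drop = TRUE]
    if (n == 1L) W <- matrix(W, 1L, L)
    st <- stats[stats$channel == ch, ]
    if (nrow(st) == 1L && st$sigma > 0) W <- W * st$sigma + st$mu
    ref <- spec$below_ref[[ch]] %||% NA_real_
    base <- (ci - 1L) * length(stat_names)
    mu <- rowMeans(W)
    out[, base + 1L] <- mu
    out[, base + 2L] <- sqrt(rowSums((W - mu)^2) / (L - 1))
    out[, base + 3L] <- do.call(pmin, as.data.frame(W))
    out[, base + 4L] <- do.call(pmax, as.data.frame(W))
    out[, base + 5L] <- W[, L]
    tt <- seq_len(L) - mean(seq_len(L))
    out[, base + 6L] <- as.vector(W %*% tt) / sum(tt^2)
    out[, base + 7L] <- if (is.na(ref)) 0 else rowSums(W < ref)
  }
  out[, length(chans) * length(stat_names) + seq_along(spec$static)] <-
    dataset$X_static
  out
}
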