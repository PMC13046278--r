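#' Build a supervised epoch dataset for one prediction horizon
#'
#' Converts a cleaned, imputed cohort into fixed-length input windows with
#' per-horizon binary labels. Steps: append the MAP-derived trend channels
#' ([augment_dynamic_features()]), z-score every dynamic channel with frozen
#' training statistics ([zscore_normalize()]; estimated here when `stats` is
#' `NULL`), label every eligible minute ([label_epochs()]) and extract the
#' `seq_len x F_dyn` window ending at each labeled minute. Epochs labeled
#' `NA` (ambiguous or in-event) are dropped and counted. One dataset is
#' built per horizon; epoch stride is 1 minute.
#'
#' @param vitals Gridded, imputed wide tibble in physical units.
#' @param cases Case table with `case_id`, `patient_id` and the static
#'   covariates of `spec`.
#' @param cfg A [label_config()].
#' @param spec A [feature_spec()].
#' @param stats Optional frozen normalization statistics
#'   (`tibble(channel, mu, sigma)` covering the derived channels) from the
#'   training cohort; estimated from `vitals` when `NULL`.
#' @return A list of class `epoch_dataset`: `X_dyn` (`n x seq_len x F_dyn`
#'   array, normalized), `X_static` (`n x F_static`), `y` (0/1), `group`
#'   (patient ids), `case_id`, `t_end`, plus metadata (`horizon`,
#'   `threshold`, `seq_len`, `feature_names`, `static_names`, `stats`,
#'   `spec`, `n_dropped`).
#' @export
build_dataset <- function(vitals, cases, cfg = label_config(),
                          spec = feature_spec(), stats = NULL) {
  assert_vitals(vitals, "MAP")
  if (nrow(vitals) == 0L) {
    return(structure(list(
      X_dyn = array(0, c(0, cfg$seq_len, length(spec$dynamic_channels)),
                    dimnames = list(NULL, NULL, spec$dynamic_channels)),
      X_static = matrix(0, 0, length(spec$static)),
      y = integer(0), group = character(0), case_id = character(0),
      t_end = integer(0), horizon = cfg$horizon, threshold = cfg$threshold,
      seq_len = cfg$seq_len, feature_names = spec$dynamic_channels,
      static_names = spec$static, stats = stats, spec = spec, n_dropped = 0L
    ), class = "epoch_dataset"))
  }
  aug <- augment_dynamic_features(vitals, spec)
  keep <- intersect(spec$dynamic_channels, names(aug))
  if (!setequal(keep, spec$dynamic_channels)) {
    abort(paste0("missing dynamic channels: ",
                 paste(setdiff(spec$dynamic_channels, keep), collapse = ", ")))
  }
  aug <- select(aug, all_of(c("case_id", "time_min", spec$dynamic_channels)))
  z <- zscore_normalize(aug, stats = stats)
  labs <- label_epochs(vitals, cfg)
  n_dropped <- sum(is.na(labs$label))
  labs <- filter(labs, !is.na(.data$label))

  F_dyn <- length(spec$dynamic_channels)
  L <- cfg$seq_len
  per_case <- split(labs, labs$case_id)
  zs <- split(z$vitals, z$vitals$case_id)
  blocks <- purrr::map(per_case, function(lb) {
    zv <- arrange(zs[[lb$case_id[1]]], .data$time_min)
    M <- as.matrix(zv[, spec$dynamic_channels])
    idx <- outer(lb$t_end + 1L, (L - 1L):0L, "-")   # rows into M (1-based)
    X <- array(NA_real_, c(nrow(lb), L, F_dyn))
    for (f in seq_len(F_dyn)) X[, , f] <- matrix(M[idx, f], nrow(lb), L)
    X
  })
  n <- nrow(labs)
  X_dyn <- array(NA_real_, c(n, L, F_dyn),
                 dimnames = list(NULL, NULL, spec$dynamic_channels))
  pos <- 0L
  for (b in blocks) {
    nb <- dim(b)[1]
    if (nb) X_dyn[pos + seq_len(nb), , ] <- b
    pos <- pos + nb
  }
  # cells still missing after imputation (leading gaps) sit at the channel
  # mean on the z-scale
  X_dyn[is.na(X_dyn)] <- 0
  labs <- bind_rows(per_case)   # same order as blocks
  cmatch <- match(labs$case_id, cases$case_id)
  if (anyNA(cmatch)) abort("case table does not cover all cases in `vitals`")
  X_static <- encode_static(cases[cmatch, ], spec)

  structure(list(
    X_dyn = X_dyn,
    X_static = X_static,
    y = as.integer(labs$label),
    group = as.character(cases$patient_id[cmatch]),
    case_id = labs$case_id,
    t_end = labs$t_end,
    horizon = cfg$horizon,
    threshold = cfg$threshold,
    seq_len = L,
    feature_names = spec$dynamic_channels,
    static_names = spec$static,
    stats = z$stats,
    spec = spec,
    n_dropped = n_dropped
  ), class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat(sprintf(paste0("<epoch_dataset> %d epochs (%d dropped), %d x %d dynamic, ",
                     "%d static; horizon %d min, threshold %g mmHg, prevalence %.3f\n"),
              length(x$y), x$n_dropped, x$seq_len, length(x$feature_names),
              length(x$static_names), x$horizon, x$threshold, mean(x$y)))
  invisible(x)
}

# Row subset of an epoch dataset (used for splits and shuffling).
dataset_subset <- function(ds, idx) {
  ds$X_dyn <- ds$X_dyn[idx, , , drop = FALSE]
  ds$X_static <- ds$X_static[idx, , drop = FALSE]
  ds$y <- ds$y[idx]
  ds$group <- ds$group[idx]
  ds$case_id <- ds$case_id[idx]
  ds$t_end <- ds$t_end[idx]
  ds
}

#' Split an epoch dataset along a patient partition
#'
#' @param dataset An `epoch_dataset`.
#' @param split A `list(train, validation)` of case tables from
#'   [split_by_patient()].
#' @return `list(train, validation)` of `epoch_dataset`s.
#' @export
dataset_split <- function(dataset, split) {
  tr <- dataset$case_id %in% split$train$case_id
  list(train = dataset_subset(dataset, which(tr)),
       validation = dataset_subset(dataset, which(!tr)))
}
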