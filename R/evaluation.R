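# Discrimination, operating-point and calibration metrics.

# Mann-Whitney AUC (ties counted 1/2) via midranks; O(n log n).
auc_point <- function(y, p) {
  y <- as.integer(y)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0L || nn == 0L) abort("AUC undefined: y has a single class")
  r <- rank(p)
  (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the ROC curve with confidence interval
#'
#' AUC by the Mann-Whitney identity (tied pairs count 1/2), equivalent to
#' trapezoidal integration of the ROC curve. The 95% CI uses a stratified
#' bootstrap (positives and negatives resampled separately, percentile
#' interval, seeded); DeLong's analytic interval is available via pROC when
#' installed.
#'
#' @param y Binary labels.
#' @param p Scores or probabilities.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param ci_method `"bootstrap"` (default) or `"delong"`.
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return Tibble `(auc, ci_lo, ci_hi, n, prevalence, ci_method)`.
#' @export
roc_auc <- function(y, p, n_boot = 1000, ci_method = c("bootstrap", "delong"),
                    conf = 0.95, seed = 1L) {
  ci_method <- match.arg(ci_method)
  y <- as.integer(y)
  a <- auc_point(y, p)
  alpha <- (1 - conf) / 2
  if (ci_method == "delong") {
    if (!requireNamespace("pROC", quietly = TRUE)) {
      abort("ci_method = 'delong' requires the pROC package")
    }
    ci <- as.numeric(pROC::ci.auc(pROC::roc(y, p, quiet = TRUE),
                                  conf.level = conf, method = "delong"))
    lo <- ci[1]; hi <- ci[3]
  } else {
    pos <- which(y == 1L); neg <- which(y == 0L)
    boots <- local_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        ip <- pos[sample.int(length(pos), replace = TRUE)]
        ineg <- neg[sample.int(length(neg), replace = TRUE)]
        auc_point(c(rep(1L, length(ip)), rep(0L, length(ineg))),
                  c(p[ip], p[ineg]))
      }, double(1))
    })
    lo <- unname(quantile(boots, alpha)); hi <- unname(quantile(boots, 1 - alpha))
  }
  tibble(auc = a, ci_lo = lo, ci_hi = hi, n = length(y),
         prevalence = mean(y), ci_method = ci_method)
}

#' Precision-recall curve and average precision
#'
#' Average precision is the step-wise integral of the PR curve:
#' `AP = sum_k (R_k - R_{k-1}) P_k` over descending score cutoffs (tied
#' scores collapsed to one operating point). A constant score yields
#' `AP = prevalence`; a perfect ranking yields 1.
#'
#' @param y Binary labels.
#' @param p Scores.
#' @return `list(curve, average_precision)`; `curve` is a tibble
#'   `(threshold, recall, precision)`.
#' @export
pr_metrics <- function(y, p) {
  y <- as.integer(y)
  P <- sum(y == 1L)
  if (P == 0L) abort("average precision undefined: no positives")
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  tp <- cumsum(ys)
  k <- seq_along(ys)
  # last index of each tie group = a distinct operating point
  last <- which(diff(c(ps, -Inf)) != 0)
  rec <- tp[last] / P
  prec <- tp[last] / k[last]
  ap <- sum(diff(c(0, rec)) * prec)
  list(curve = tibble(threshold = ps[last], recall = rec, precision = prec),
       average_precision = ap)
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Predictions are positive when `p >= threshold` (ties at the threshold
#' count as positive). PPV and F1 are `NA` when undefined (no predicted
#' positives).
#'
#' @param y Binary labels.
#' @param p Probabilities.
#' @param threshold Decision threshold.
#' @return One-row tibble `(threshold, tp, fp, fn, tn, accuracy, f1, ppv,
#'   recall, specificity, n, prevalence)`.
#' @export
classification_metrics <- function(y, p, threshold = 0.5) {
  if (inherits(threshold, "threshold_choice")) threshold <- threshold$threshold
  y <- as.integer(y)
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(rec) && ppv + rec > 0) {
    2 * ppv * rec / (ppv + rec)
  } else NA_real_
  tibble(threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn,
         accuracy = (tp + tn) / length(y), f1 = f1, ppv = ppv, recall = rec,
         specificity = spec, n = length(y), prevalence = mean(y))
}

#' Select a decision threshold on the internal validation set
#'
#' Strategies: `"youden"` maximizes TPR - FPR over all observed cutoffs and
#' returns the midpoint between the optimal cutoff and the next lower
#' distinct score (on perfectly separated scores this is the midpoint of
#' the gap between classes); `"fixed_recall"` returns the largest threshold
#' whose recall on the selection set is at least `target` (maximizing
#' specificity subject to the recall floor); `"fixed_prob"` returns
#' `target` unchanged. The choice is recorded for provenance.
#'
#' @param y Labels of the selection (validation) set.
#' @param p Probabilities on the selection set.
#' @param strategy `"youden"`, `"fixed_recall"` or `"fixed_prob"`.
#' @param target Recall floor or fixed probability, per strategy.
#' @return A list of class `threshold_choice`: `(threshold, strategy,
#'   target)`.
#' @export
select_threshold <- function(y, p, strategy = c("youden", "fixed_recall",
                                                "fixed_prob"), target = NULL) {
  strategy <- match.arg(strategy)
  y <- as.integer(y)
  thr <- switch(strategy,
    youden = {
      u <- sort(unique(p))
      j <- vapply(u, function(t) {
        pred <- p >= t
        mean(pred[y == 1L]) - mean(pred[y == 0L])
      }, double(1))
      ustar <- u[which.max(j)]
      lower <- u[u < ustar]
      if (length(lower)) (ustar + max(lower)) / 2 else ustar
    },
    fixed_recall = {
      if (is.null(target)) abort("fixed_recall requires `target`")
      u <- sort(unique(p), decreasing = TRUE)
      rec <- vapply(u, function(t) mean(p[y == 1L] >= t), double(1))
      ok <- which(rec >= target)
      if (length(ok)) u[ok[1]] else min(p)
    },
    fixed_prob = {
      if (is.null(target)) abort("fixed_prob requires `target`")
      target
    }
  )
  structure(list(threshold = thr, strategy = strategy, target = target),
            class = "threshold_choice")
}

#' Expected calibration error with reliability bins
#'
#' Predictions are binned into `n_bins` equal-width bins on `[0, 1]`
#' (`p = 1` falls in the last bin); the ECE is the bin-weight-averaged
#' absolute gap between mean predicted probability (confidence) and
#' observed event frequency. The 95% CI is a seeded percentile bootstrap
#' over observations.
#'
#' @param y Binary labels.
#' @param p Probabilities in `[0, 1]`.
#' @param n_bins Number of bins (default 10; must be >= 2).
#' @param n_boot Bootstrap resamples (default 1000; 0 skips the CI).
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return A list of class `calibration_report`: `bins` (tibble with bin
#'   edges, confidence, observed frequency, weight, count), `ece`,
#'   `ci_lo`, `ci_hi`, `n_bins`, `n`.
#' @export
ece <- function(y, p, n_bins = 10, n_boot = 1000, conf = 0.95, seed = 1L) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  y <- as.integer(y)
  point <- ece_point(y, p, n_bins)
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    alpha <- (1 - conf) / 2
    boots <- local_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(y), replace = TRUE)
        ece_point(y[idx], p[idx], n_bins)$ece
      }, double(1))
    })
    lo <- unname(quantile(boots, alpha)); hi <- unname(quantile(boots, 1 - alpha))
  }
  structure(list(bins = point$bins, ece = point$ece, ci_lo = lo, ci_hi = hi,
                 n_bins = n_bins, n = length(y)),
            class = "calibration_report")
}

ece_point <- function(y, p, n_bins) {
  bin <- pmin(floor(p * n_bins) + 1L, n_bins)
  n <- length(y)
  cnt <- tabulate(bin, n_bins)
  conf_b <- vapply(seq_len(n_bins), function(b) {
    if (cnt[b]) mean(p[bin == b]) else NA_real_
  }, double(1))
  acc_b <- vapply(seq_len(n_bins), function(b) {
    if (cnt[b]) mean(y[bin == b]) else NA_real_
  }, double(1))
  w <- cnt / n
  bins <- tibble(bin = seq_len(n_bins),
                 lo = (seq_len(n_bins) - 1) / n_bins,
                 hi = seq_len(n_bins) / n_bins,
                 confidence = conf_b, observed = acc_b, weight = w, n = cnt)
  list(bins = bins, ece = sum(w * abs(acc_b - conf_b), na.rm = TRUE))
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> ECE %.4f (%.4f, %.4f), %d bins, n = %d\n",
              x$ece, x$ci_lo, x$ci_hi, x$n_bins, x$n))
  invisible(x)
}

#' @export
tidy.calibration_report <- function(x, ...) x$bins

#' @export
glance.calibration_report <- function(x, ...) {
  tibble(ece = x$ece, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
         n_bins = x$n_bins, n = x$n)
}

#' Full metrics report (discrimination + operating point)
#'
#' Assembles the Table-2-style row: confusion metrics at the stated
#' threshold plus AUC with CI and average precision.
#'
#' @inheritParams classification_metrics
#' @param n_boot Bootstrap resamples for the AUC CI.
#' @param seed Bootstrap seed.
#' @param subgroup Optional subgroup tag.
#' @return One-row tibble.
#' @export
metrics_report <- function(y, p, threshold = 0.5, n_boot = 1000, seed = 1L,
                           subgroup = NA_character_) {
  cm <- classification_metrics(y, p, threshold)
  ra <- roc_auc(y, p, n_boot = n_boot, seed = seed)
  ap <- pr_metrics(y, p)$average_precision
  dplyr::bind_cols(tibble(subgroup = subgroup), cm,
                   tibble(auc = ra$auc, auc_lo = ra$ci_lo, auc_hi = ra$ci_hi,
                          average_precision = ap))
}

#' Stratified (subgroup) evaluation with a shared threshold
#'
#' Computes a [metrics_report()] per stratum — e.g., age < 65 vs >= 65
#' years, or ASA <= II vs >= III — using one decision threshold for all
#' strata, so operating points are comparable across subgroups.
#'
#' @param y,p Labels and probabilities.
#' @param group Stratum membership, same length as `y`.
#' @param threshold Shared decision threshold (or `threshold_choice`).
#' @param n_boot,seed AUC bootstrap controls.
#' @return Tibble with one `metrics_report()` row per stratum.
#' @export
evaluate_subgroups <- function(y, p, group, threshold = 0.5, n_boot = 200,
                               seed = 1L) {
  stopifnot(length(group) == length(y))
  purrr::map_dfr(split(seq_along(y), group), function(idx) {
    metrics_report(y[idx], p[idx], threshold, n_boot = n_boot, seed = seed,
                   subgroup = as.character(group[idx[1]]))
  })
}
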