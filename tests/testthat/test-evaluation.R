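test_that("AUC matches exhaustive pair counting and handles edge cases", {
  # perfect separation
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), n_boot = 0)$auc, 1)
  expect_error(roc_auc(rep(1, 5), runif(5)), "single class")

  set.seed(21)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    expect_equal(iohcast:::auc_point(y, p), ref_auc(y, p), tolerance = 1e-12)
  }

  # invariance under strictly increasing transforms
  set.seed(22)
  y <- rbinom(300, 1, 0.3)
  y[1:2] <- c(0, 1)
  p <- runif(300)
  a1 <- iohcast:::auc_point(y, p)
  expect_equal(iohcast:::auc_point(y, qlogis(p * 0.98 + 0.01)), a1,
               tolerance = 1e-12)
  expect_equal(iohcast:::auc_point(y, p^3), a1, tolerance = 1e-12)

  # null data: AUC near 1/2
  set.seed(23)
  yn <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(iohcast:::auc_point(yn, runif(1e4)) - 0.5), 0.02)
})

test_that("AUC confidence intervals are sane and agree with DeLong", {
  set.seed(24)
  y <- rbinom(400, 1, 0.3)
  y[1:2] <- c(0, 1)
  p <- plogis(y * 1.2 + rnorm(400))
  r <- roc_auc(y, p, n_boot = 500, seed = 2)
  expect_true(r$ci_lo <= r$auc && r$auc <= r$ci_hi)
  d <- roc_auc(y, p, ci_method = "delong")
  expect_equal(d$auc, r$auc, tolerance = 1e-12)
  expect_equal(r$ci_lo, d$ci_lo, tolerance = 0.03)
  expect_equal(r$ci_hi, d$ci_hi, tolerance = 0.03)
})

test_that("average precision matches the step-wise oracle", {
  expect_equal(pr_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$average_precision, 1)
  # constant score: AP equals prevalence
  y <- c(1, 0, 0, 1, 0, 0, 0, 0, 1, 0)
  expect_equal(pr_metrics(y, rep(0.4, 10))$average_precision, mean(y),
               tolerance = 1e-12)
  set.seed(25)
  for (i in 1:50) {
    n <- sample(10:150, 1)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    p <- round(runif(n), 2)
    expect_equal(pr_metrics(y, p)$average_precision, ref_average_precision(y, p),
                 tolerance = 1e-12)
  }
})

test_that("classification metrics recover printed confusion arithmetic", {
  # construct TP=8, FP=2, FN=1, TN=9 at threshold 0.5
  y <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))
  p <- c(rep(0.9, 8), rep(0.9, 2), rep(0.1, 1), rep(0.1, 9))
  m <- classification_metrics(y, p, 0.5)
  expect_equal(m$tp, 8); expect_equal(m$fp, 2)
  expect_equal(m$fn, 1); expect_equal(m$tn, 9)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$accuracy, 17 / 20)

  set.seed(26)
  yy <- rbinom(100, 1, 0.4); pp <- runif(100)
  lo <- classification_metrics(yy, pp, 0)
  expect_equal(lo$recall, 1); expect_equal(lo$specificity, 0)
  hi <- classification_metrics(yy, pp, 1 + 1e-9)
  expect_equal(hi$recall, 0); expect_equal(hi$specificity, 1)
})

test_that("threshold selection strategies meet their contracts", {
  # youden on separated data returns the midpoint of the class gap
  y <- c(0, 0, 0, 1, 1)
  p <- c(0.1, 0.15, 0.2, 0.8, 0.9)
  ch <- select_threshold(y, p, "youden")
  expect_equal(ch$threshold, 0.5)
  expect_equal(ch$strategy, "youden")

  # youden equals brute force over all cut candidates
  set.seed(27)
  for (i in 1:30) {
    yy <- rbinom(60, 1, 0.4)
    if (length(unique(yy)) < 2) yy[1:2] <- c(0, 1)
    pp <- round(runif(60), 2)
    thr <- select_threshold(yy, pp, "youden")$threshold
    j_at <- function(t) mean(pp[yy == 1] >= t) - mean(pp[yy == 0] >= t)
    best_j <- max(vapply(sort(unique(pp)), j_at, double(1)))
    expect_equal(j_at(thr), best_j, tolerance = 1e-12)
  }

  # fixed recall achieves the floor on the selection set
  set.seed(28)
  yy <- rbinom(300, 1, 0.3); yy[1:2] <- c(0, 1)
  pp <- plogis(yy + rnorm(300))
  fr <- select_threshold(yy, pp, "fixed_recall", target = 0.9)
  expect_gte(classification_metrics(yy, pp, fr$threshold)$recall, 0.9)
  expect_equal(select_threshold(yy, pp, "fixed_prob", target = 0.42)$threshold,
               0.42)
})

test_that("expected calibration error matches the binning oracle", {
  # exact predictions and prevalence-constant predictions are calibrated
  y <- rbinom(200, 1, 0.5)
  expect_equal(ece(y, as.numeric(y), n_boot = 0)$ece, 0)
  expect_equal(ece(y, rep(mean(y), 200), n_boot = 0)$ece, 0)
  expect_error(ece(y, as.numeric(y), n_bins = 1), "n_bins")
  expect_error(ece(y, y + 2), "probabilities")

  set.seed(29)
  for (i in 1:50) {
    n <- sample(20:300, 1)
    yy <- rbinom(n, 1, 0.4)
    pp <- runif(n)
    nb <- sample(c(5L, 10L, 20L), 1)
    r <- ece(yy, pp, n_bins = nb, n_boot = 0)
    expect_equal(r$ece, ref_ece(yy, pp, nb), tolerance = 1e-12)
    expect_equal(sum(r$bins$weight), 1, tolerance = 1e-12)
  }
})

test_that("bootstrap intervals cover the estimate and shrink with n", {
  set.seed(30)
  n <- 6400
  y <- rbinom(n, 1, 0.4)
  p <- plogis(qlogis(0.4) + y + rnorm(n) - 0.4)
  p <- pmin(pmax(p, 0), 1)
  r_small <- ece(y[1:400], p[1:400], seed = 3)
  r_big <- ece(y, p, seed = 3)
  expect_true(r_small$ci_lo <= r_small$ece && r_small$ece <= r_small$ci_hi)
  w_small <- r_small$ci_hi - r_small$ci_lo
  w_big <- r_big$ci_hi - r_big$ci_lo
  # 16x the data: width should fall roughly like 1/sqrt(n)
  expect_lt(w_big, 0.6 * w_small)
})

test_that("subgroup evaluation partitions the cohort at a shared threshold", {
  set.seed(31)
  n <- 600
  y <- rbinom(n, 1, 0.3); y[1:4] <- c(0, 1, 0, 1)
  p <- plogis(y + rnorm(n))
  grp <- rep(c("age<65", "age>=65"), length.out = n)
  reps <- evaluate_subgroups(y, p, grp, threshold = 0.5, n_boot = 50)
  expect_equal(nrow(reps), 2)
  expect_equal(sum(reps$n), n)
  pooled <- classification_metrics(y, p, 0.5)
  expect_equal(sum(reps$tp), pooled$tp)
  expect_equal(sum(reps$fp), pooled$fp)
  expect_equal(sum(reps$fn), pooled$fn)
  expect_equal(sum(reps$tn), pooled$tn)
  # a single stratum reproduces the global report
  solo <- evaluate_subgroups(y, p, rep("all", n), threshold = 0.5, n_boot = 50)
  expect_equal(solo$accuracy, pooled$accuracy)
  expect_equal(solo$auc, roc_auc(y, p, n_boot = 0)$auc)
})
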