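# Tiny architecture used throughout: big enough to exercise multi-head
# attention and stacking, small enough for numeric differentiation.
tiny_cfg <- function(dropout = 0) {
  model_config(n_layers = 2, n_heads = 2, d_model = 8, d_ff = 16,
               conv_kernel = 3, seq_len = 5, f_dyn = 3, f_static = 2,
               dropout = dropout, lr = 1e-3, batch_size = 16,
               max_epochs = 4, eval_every = 1, patience = 4)
}

tiny_batch <- function(B = 6, seed = 1) {
  set.seed(seed)
  list(X = array(rnorm(B * 5 * 3), c(B, 5, 3)),
       S = matrix(rnorm(B * 2), B, 2),
       y = rep_len(c(1L, 0L), B))
}

test_that("compiled forward pass matches the independent R reference", {
  cfg <- tiny_cfg()
  m <- build_transformer(cfg, seed = 42)
  b <- tiny_batch(B = 7)
  got <- iohcast:::tf_logits(m$params, cfg, b$X, b$S)$logits
  ref <- ref_transformer_forward(m$params, cfg, b$X, b$S)
  expect_equal(got, ref, tolerance = 1e-5)
  # probabilities are valid and shaped per batch
  p <- plogis(got)
  expect_length(p, 7)
  expect_true(all(p > 0 & p < 1))
})

test_that("analytic gradients match numeric differentiation of the reference", {
  cfg <- tiny_cfg()
  m <- build_transformer(cfg, seed = 42)
  b <- tiny_batch(B = 4)
  fw <- iohcast:::tf_logits(m$params, cfg, b$X, b$S, keep_cache = TRUE)
  cl <- iohcast:::composite_loss(fw$logits, b$y, 0.6, 2, 0.5)
  g <- iohcast:::tf_backward(fw$cache, cl$grad)
  loss_ref <- function(p) {
    s <- ref_transformer_forward(p, cfg, b$X, b$S)
    iohcast:::composite_loss(s, b$y, 0.6, 2, 0.5)$loss
  }
  set.seed(7)
  idx <- sort(sample(length(m$params), 120))
  h <- 1e-5
  num <- vapply(idx, function(i) {
    up <- m$params; up[i] <- up[i] + h
    dn <- m$params; dn[i] <- dn[i] - h
    (loss_ref(up) - loss_ref(dn)) / (2 * h)
  }, double(1))
  rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-3)
  expect_lt(max(rel), 1e-3)
})

test_that("initialization is seed-deterministic and config-validated", {
  cfg <- tiny_cfg()
  expect_identical(build_transformer(cfg, seed = 5)$params,
                   build_transformer(cfg, seed = 5)$params)
  expect_false(identical(build_transformer(cfg, seed = 5)$params,
                         build_transformer(cfg, seed = 6)$params))
  expect_error(model_config(d_model = 10, n_heads = 4), "divisible")
  expect_error(model_config(conv_kernel = 4), "odd")
  expect_equal(build_transformer(cfg)$n_params,
               iohcast:::tf_nparams(iohcast:::tf_cfg_list(cfg)))
})

test_that("samples are processed independently (permutation equivariance)", {
  cfg <- tiny_cfg()
  m <- build_transformer(cfg, seed = 9)
  b <- tiny_batch(B = 8, seed = 3)
  base <- iohcast:::tf_logits(m$params, cfg, b$X, b$S)$logits
  set.seed(4)
  perm <- sample(8)
  got <- iohcast:::tf_logits(m$params, cfg,
                             b$X[perm, , , drop = FALSE],
                             b$S[perm, , drop = FALSE])$logits
  expect_equal(got, base[perm], tolerance = 1e-5)
})

tiny_dataset <- function(n = 160, seed = 1, F_dyn = 3, L = 5, permute = FALSE) {
  set.seed(seed)
  # planted signal: the label follows the last-minute mean of channel 1
  X <- array(rnorm(n * L * F_dyn), c(n, L, F_dyn))
  s <- X[, L, 1] + 0.5 * X[, L - 1, 1]
  y <- as.integer(runif(n) < plogis(2 * s))
  if (permute) y <- sample(y)
  structure(list(
    X_dyn = X, X_static = matrix(0, n, 2), y = y,
    group = paste0("p", rep(seq_len(n / 4), each = 4)),
    case_id = paste0("c", seq_len(n)), t_end = rep(10L, n),
    horizon = 5L, threshold = 65, seq_len = L,
    feature_names = paste0("f", seq_len(F_dyn)), static_names = c("age", "sex"),
    stats = tibble::tibble(channel = paste0("f", seq_len(F_dyn)), mu = 0, sigma = 1),
    spec = feature_spec(), n_dropped = 0L
  ), class = "epoch_dataset")
}

test_that("training enforces the leakage and label contracts", {
  tr <- tiny_dataset(seed = 1)
  va <- tiny_dataset(seed = 2)
  va$group <- paste0("q", seq_along(va$y) %% 10)
  bad_va <- tiny_dataset(seed = 3)   # shares patient ids with tr
  expect_error(train_transformer(NULL, tr, bad_va, cfg = tiny_cfg()),
               "share patients")
  single <- tr
  single$y <- rep(1L, length(single$y))
  expect_error(train_transformer(NULL, single, va, cfg = tiny_cfg()),
               "single-class")
})

test_that("training reduces the loss, keeps the best checkpoint, and is reproducible", {
  tr <- tiny_dataset(n = 240, seed = 5)
  va <- tiny_dataset(n = 120, seed = 6)
  va$group <- paste0("q", seq_along(va$y) %% 10)
  cfg <- tiny_cfg(dropout = 0.1)
  cfg$max_epochs <- 6L
  fit <- train_transformer(NULL, tr, va, cfg = cfg, seed = 11)
  h <- tidy(fit)
  expect_gt(nrow(h), 2)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # best checkpoint is never worse than any evaluated epoch
  expect_equal(fit$best_val_loss, min(h$val_loss), tolerance = 1e-12)
  # rerun with the same seed reproduces the history
  fit2 <- train_transformer(NULL, tr, va, cfg = cfg, seed = 11)
  expect_equal(tidy(fit2), h, tolerance = 1e-10)
  # inference is deterministic
  p1 <- predict_proba(fit, va)
  p2 <- predict_proba(fit, va)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("lambda 0 training equals a pure focal-loss run", {
  tr <- tiny_dataset(n = 160, seed = 7)
  va <- tiny_dataset(n = 80, seed = 8)
  va$group <- paste0("q", seq_along(va$y) %% 10)
  cfg0 <- tiny_cfg()
  cfg0$rank_weight <- 0
  cfg0$max_epochs <- 2L
  fitA <- train_transformer(NULL, tr, va, cfg = cfg0, seed = 4)
  fitB <- train_transformer(NULL, tr, va, cfg = cfg0, seed = 4)
  expect_identical(fitA$params, fitB$params)
  # with the ranking term the trajectory differs
  cfg1 <- cfg0
  cfg1$rank_weight <- 0.5
  fitC <- train_transformer(NULL, tr, va, cfg = cfg1, seed = 4)
  expect_false(identical(fitA$params, fitC$params))
})

test_that("predicted probabilities are calibrated in the large on easy data", {
  tr <- tiny_dataset(n = 400, seed = 9)
  va <- tiny_dataset(n = 200, seed = 10)
  va$group <- paste0("q", seq_along(va$y) %% 10)
  cfg <- tiny_cfg()
  cfg$max_epochs <- 8L
  fit <- train_transformer(NULL, tr, va, cfg = cfg, seed = 2)
  p <- predict_proba(fit, va)
  expect_lt(abs(mean(p) - mean(va$y)), 0.05)
})
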