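#' Transformer model configuration
#'
#' Architecture and training hyperparameters of the IOH classifier: an
#' 8-layer Transformer encoder with 8 attention heads, model dimension 64
#' and feed-forward dimension 256, dropout 0.1, preceded by a Conv1D
#' (kernel 3, same padding) over the 15-timepoint input window and followed
#' by global average pooling, concatenation of the 2 static covariates and
#' a sigmoid head. Training uses AdamW (learning rate 2e-4), a composite
#' loss of focal loss (alpha 0.6, gamma 2) plus `rank_weight` times a
#' pairwise AUC-ranking surrogate, validation-loss monitoring every
#' `eval_every` epochs, and early stopping after `patience` consecutive
#' evaluations without improvement (set `patience_unit = "epochs"` to
#' monitor every epoch instead).
#'
#' @param n_layers,n_heads,d_model,d_ff,dropout Encoder architecture.
#' @param conv_kernel Conv1D kernel width in minutes (odd).
#' @param seq_len,f_dyn,f_static Input window shape.
#' @param lr Learning rate.
#' @param batch_size Batch size (400-1000 printed range; default 512).
#' @param max_epochs Maximum training epochs (default 200).
#' @param focal_alpha,focal_gamma Focal-loss parameters.
#' @param rank_weight Weight lambda of the AUC-ranking term (>= 0).
#' @param eval_every Epochs between validation evaluations.
#' @param patience Evaluations (or epochs) without improvement before stop.
#' @param patience_unit `"evaluations"` (default) or `"epochs"`.
#' @param weight_decay AdamW decoupled weight decay.
#' @param max_pairs Ranking-loss pair subsample cap per batch.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_layers = 8, n_heads = 8, d_model = 64, d_ff = 256,
                         dropout = 0.1, conv_kernel = 3, seq_len = 15,
                         f_dyn = 17, f_static = 2, lr = 2e-4, batch_size = 512,
                         max_epochs = 200, focal_alpha = 0.6, focal_gamma = 2,
                         rank_weight = 0.5, eval_every = 10, patience = 3,
                         patience_unit = c("evaluations", "epochs"),
                         weight_decay = 0.01, max_pairs = 1e4) {
  if (d_model %% n_heads != 0) abort("d_model must be divisible by n_heads")
  if (conv_kernel %% 2 == 0) abort("conv_kernel must be odd")
  if (batch_size < 1) abort("batch_size must be positive")
  if (rank_weight < 0) abort("rank_weight must be >= 0")
  for (nm in c("n_layers", "n_heads", "d_model", "d_ff", "seq_len", "f_dyn",
               "f_static", "lr", "max_epochs", "eval_every", "patience")) {
    stopifnot_scalar_number(get(nm), nm, lower = 1e-12)
  }
  structure(list(
    n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
    d_model = as.integer(d_model), d_ff = as.integer(d_ff),
    dropout = dropout, conv_kernel = as.integer(conv_kernel),
    seq_len = as.integer(seq_len), f_dyn = as.integer(f_dyn),
    f_static = as.integer(f_static), lr = lr,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    focal_alpha = focal_alpha, focal_gamma = focal_gamma,
    rank_weight = rank_weight, eval_every = as.integer(eval_every),
    patience = as.integer(patience), patience_unit = match.arg(patience_unit),
    weight_decay = weight_decay, max_pairs = max_pairs
  ), class = "model_config")
}

# Flat parameter layout mirroring the compiled side; offsets are 0-based.
param_layout <- function(cfg) {
  d <- cfg$d_model; dff <- cfg$d_ff
  specs <- list(c("conv_W", cfg$conv_kernel * cfg$f_dyn * d, cfg$f_dyn),
                c("conv_b", d, NA))
  for (l in seq_len(cfg$n_layers)) {
    specs <- c(specs, lapply(list(
      c("ln1_g", d, NA), c("ln1_b", d, NA),
      c("Wq", d * d, d), c("bq", d, NA), c("Wk", d * d, d), c("bk", d, NA),
      c("Wv", d * d, d), c("bv", d, NA), c("Wo", d * d, d), c("bo", d, NA),
      c("ln2_g", d, NA), c("ln2_b", d, NA),
      c("W1", d * dff, d), c("b1", dff, NA),
      c("W2", dff * d, dff), c("b2", d, NA)
    ), function(s) c(paste0("l", l, "_", s[1]), s[2], s[3])))
  }
  specs <- c(specs, list(c("lnf_g", d, NA), c("lnf_b", d, NA),
                         c("head_w", d + cfg$f_static, d + cfg$f_static),
                         c("head_b", 1, NA)))
  off <- 0L
  out <- purrr::map_dfr(specs, function(s) {
    n <- as.integer(s[2])
    row <- tibble(name = s[1], offset = off, n = n,
                  fan_in = suppressWarnings(as.integer(s[3])))
    off <<- off + n
    row
  })
  out
}

tf_cfg_list <- function(cfg) {
  cfg[c("seq_len", "f_dyn", "f_static", "d_model", "n_heads", "n_layers",
        "d_ff", "conv_kernel")]
}

#' Build an untrained Transformer classifier
#'
#' Allocates and initializes the flat parameter vector: Glorot-uniform
#' weights, zero biases, unit layer-norm gains. Two builds with the same
#' seed have identical initial weights.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the initialization.
#' @return A list of class `ioh_transformer` with elements `params`, `cfg`,
#'   `layout`, `n_params`, `history` and `stats` (normalization statistics,
#'   attached at training time).
#' @export
build_transformer <- function(cfg = model_config(), seed = 1L) {
  layout <- param_layout(cfg)
  n_total <- sum(layout$n)
  stopifnot(n_total == tf_nparams(tf_cfg_list(cfg)))
  params <- local_seed(seed, {
    p <- numeric(n_total)
    for (i in seq_len(nrow(layout))) {
      nm <- layout$name[i]
      idx <- layout$offset[i] + seq_len(layout$n[i])
      if (grepl("_g$", nm)) {
        p[idx] <- 1
      } else if (grepl("(_b|_b\\d*)$", nm) || grepl("b[qkvo12]$", nm) ||
                 nm == "head_b" || nm == "conv_b") {
        p[idx] <- 0
      } else {
        fan_in <- layout$fan_in[i]
        fan_out <- layout$n[i] / max(fan_in, 1L)
        lim <- sqrt(6 / (fan_in + fan_out))
        p[idx] <- runif(layout$n[i], -lim, lim)
      }
    }
    p
  })
  structure(list(params = params, cfg = cfg, layout = layout,
                 n_params = n_total, history = NULL, stats = NULL,
                 trained = FALSE),
            class = "ioh_transformer")
}

#' @export
print.ioh_transformer <- function(x, ...) {
  cat(sprintf("<ioh_transformer> %d layers, %d heads, d_model %d; %s; %d parameters\n",
              x$cfg$n_layers, x$cfg$n_heads, x$cfg$d_model,
              if (x$trained) "trained" else "untrained", x$n_params))
  invisible(x)
}

batch_array <- function(ds, idx) {
  list(X = ds$X_dyn[idx, , , drop = FALSE],
       S = ds$X_static[idx, , drop = FALSE],
       y = ds$y[idx])
}

tf_logits <- function(params, cfg, X, S, dropout = 0, seed = 0L,
                      keep_cache = FALSE) {
  tf_forward(params, tf_cfg_list(cfg), X, S, dropout, as.integer(seed),
             keep_cache)
}

# Composite validation loss, deterministic: the ranking pairs are
# subsampled under a fixed seed so successive evaluations are comparable.
val_loss_of <- function(params, cfg, ds, chunk = 4096L) {
  n <- length(ds$y)
  s <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    b <- batch_array(ds, idx)
    s[idx] <- tf_logits(params, cfg, b$X, b$S)$logits
  }
  cl <- local_seed(1L, composite_loss(s, ds$y, cfg$focal_alpha, cfg$focal_gamma,
                                      cfg$rank_weight, max_pairs = 1e5))
  list(loss = cl$loss, logits = s)
}

#' Train the Transformer with the composite focal + ranking loss
#'
#' Mini-batch AdamW training. The total loss is
#' `focal + rank_weight * ranking`; validation loss is evaluated every
#' `eval_every` epochs and training stops after `patience` consecutive
#' evaluations without improvement or at `max_epochs`. The returned model
#' carries the best-validation checkpoint and the evaluation history.
#' Training and validation sets must be patient-disjoint (asserted);
#' single-class training labels are an error.
#'
#' @param model An [build_transformer()] model (built here when `NULL`).
#' @param train,validation `epoch_dataset`s from [build_dataset()] /
#'   [dataset_split()].
#' @param cfg A [model_config()] (defaults to `model$cfg`).
#' @param seed Integer seed driving shuffling, dropout and pair subsampling.
#' @param verbose Print evaluation lines.
#' @return The trained `ioh_transformer`, with `history` (one row per
#'   evaluation: epoch, mean training loss, validation loss, validation
#'   AUC) and the dataset's normalization statistics attached.
#' @export
train_transformer <- function(model = NULL, train, validation,
                              cfg = NULL, seed = 1L, verbose = FALSE) {
  cfg <- cfg %||% model$cfg %||% model_config()
  if (is.null(model)) model <- build_transformer(cfg, seed = child_seed(seed, 97))
  if (length(unique(train$y)) < 2L) abort("training labels are single-class")
  if (length(intersect(unique(train$group), unique(validation$group)))) {
    abort("training and validation sets share patients")
  }
  if (dim(train$X_dyn)[3] != cfg$f_dyn) {
    abort(sprintf("dataset has %d dynamic features, config expects %d",
                  dim(train$X_dyn)[3], cfg$f_dyn))
  }
  eval_every <- if (cfg$patience_unit == "epochs") 1L else cfg$eval_every

  n <- length(train$y)
  params <- model$params
  m <- numeric(length(params)); v <- numeric(length(params))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_evals <- 0L
  hist <- list()

  local_seed(seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_losses <- numeric(length(starts))
      for (k in seq_along(starts)) {
        idx <- ord[starts[k]:min(n, starts[k] + cfg$batch_size - 1L)]
        b <- batch_array(train, idx)
        step <- step + 1L
        fw <- tf_logits(params, cfg, b$X, b$S, dropout = cfg$dropout,
                        seed = child_seed(seed, step), keep_cache = TRUE)
        cl <- composite_loss(fw$logits, b$y, cfg$focal_alpha, cfg$focal_gamma,
                             cfg$rank_weight, cfg$max_pairs)
        ep_losses[k] <- cl$loss
        g <- tf_backward(fw$cache, cl$grad)
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        mh <- m / (1 - beta1^step)
        vh <- v / (1 - beta2^step)
        params <- params - cfg$lr * (mh / (sqrt(vh) + adam_eps) +
                                       cfg$weight_decay * params)
      }
      if (epoch %% eval_every == 0L || epoch == cfg$max_epochs) {
        vl <- val_loss_of(params, cfg, validation)
        auc <- auc_point(validation$y, plogis(vl$logits))
        hist[[length(hist) + 1L]] <- tibble(
          epoch = epoch, train_loss = mean(ep_losses),
          val_loss = vl$loss, val_auc = auc
        )
        if (verbose) {
          inform(sprintf("epoch %d: train %.4f val %.4f auc %.3f",
                         epoch, mean(ep_losses), vl$loss, auc))
        }
        if (vl$loss < best$loss - 1e-9) {
          best <- list(loss = vl$loss, params = params, epoch = epoch)
          bad_evals <- 0L
        } else {
          bad_evals <- bad_evals + 1L
          if (bad_evals >= cfg$patience) break
        }
      }
    }
  })

  model$params <- best$params
  model$cfg <- cfg
  model$history <- bind_rows(hist)
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$loss
  model$stats <- train$stats
  model$feature_names <- train$feature_names
  model$spec <- train$spec
  model$horizon <- train$horizon
  model$trained <- TRUE
  model
}

#' Predict IOH probabilities for an epoch dataset
#'
#' Deterministic inference (dropout off): repeated calls return identical
#' probabilities in `[0, 1]`.
#'
#' @param model A trained `ioh_transformer`.
#' @param dataset An `epoch_dataset` (must match the model's feature set).
#' @param chunk Batch size for chunked inference.
#' @return Numeric vector of probabilities, one per epoch.
#' @export
predict_proba <- function(model, dataset, chunk = 4096L) {
  n <- length(dataset$y)
  if (n == 0L) return(numeric(0))
  s <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    b <- batch_array(dataset, idx)
    s[idx] <- tf_logits(model$params, model$cfg, b$X, b$S)$logits
  }
  plogis(s)
}

#' @export
tidy.ioh_transformer <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), train_loss = double(),
                        val_loss = double(), val_auc = double())
}

#' @export
glance.ioh_transformer <- function(x, ...) {
  tibble(n_params = x$n_params,
         n_layers = x$cfg$n_layers,
         trained = x$trained,
         best_epoch = x$best_epoch %||% NA_integer_,
         best_val_loss = x$best_val_loss %||% NA_real_,
         final_val_auc = if (!is.null(x$history) && nrow(x$history)) {
           x$history$val_auc[which.min(x$history$val_loss)]
         } else NA_real_)
}
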