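#' Focal loss for imbalanced binary classification
#'
#' Cross-entropy variant that down-weights well-classified examples by
#' `(1 - p)^gamma` and weights the positive class by `alpha`:
#' `FL = -alpha (1-p)^gamma log p` for `y = 1` and
#' `-(1-alpha) p^gamma log(1-p)` for `y = 0`, averaged over the batch.
#' With `gamma = 0, alpha = 0.5` it reduces to half the binary
#' cross-entropy. Probabilities are clamped to `[eps, 1-eps]`.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (0/1).
#' @param alpha Positive-class weight (default 0.6).
#' @param gamma Focusing exponent (default 2).
#' @param eps Clamp tolerance (default 1e-7).
#' @return Mean loss (scalar).
#' @export
#' @examples
#' focal_loss(0.5, 1)            # 0.6 * 0.25 * log(2)
#' focal_loss(0.7, 1, 0.5, 0)    # 0.5 * -log(0.7)
focal_loss <- function(p, y, alpha = 0.6, gamma = 2, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  y <- as.numeric(y)
  l <- ifelse(y == 1,
              -alpha * (1 - p)^gamma * log(p),
              -(1 - alpha) * p^gamma * log(1 - p))
  mean(l)
}

# Gradient of the mean focal loss w.r.t. the logit s (p = sigmoid(s)).
# Uses dp/ds = p(1-p); returns a vector of the same length as p.
focal_loss_grad_logit <- function(p, y, alpha = 0.6, gamma = 2, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  y <- as.numeric(y)
  n <- length(p)
  # y=1: dL/dp = -alpha * (1-p)^(g-1) * ((1-p)/p - g*(-log p)) ... derived:
  # d/dp[-(1-p)^g log p] = g(1-p)^(g-1) log p - (1-p)^g / p
  dldp_pos <- alpha * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
  dldp_neg <- (1 - alpha) * (-gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p))
  dldp <- ifelse(y == 1, dldp_pos, dldp_neg)
  dldp * p * (1 - p) / n
}

#' Pairwise AUC-ranking loss
#'
#' Differentiable surrogate of 1 - AUC: the mean over positive-negative
#' score pairs of `softplus(s_neg - s_pos)` (RankNet-style). Perfectly
#' separated scores drive the loss to 0; a tied pair contributes `log 2`.
#' When the number of pairs exceeds `max_pairs` a random subsample is used.
#' Returns 0 when either class is absent.
#'
#' @param s_pos Scores (logits) of positive examples.
#' @param s_neg Scores of negative examples.
#' @param max_pairs Pair subsample cap (default 1e4).
#' @return Mean pairwise loss (scalar).
#' @export
#' @examples
#' auc_rank_loss(c(3, 4), c(-3, -4))  # ~ 0
#' auc_rank_loss(0, 0)                # log(2)
auc_rank_loss <- function(s_pos, s_neg, max_pairs = 1e4) {
  np <- length(s_pos); nn <- length(s_neg)
  if (np == 0L || nn == 0L) return(0)
  pairs <- rank_pairs(np, nn, max_pairs)
  d <- s_neg[pairs$j] - s_pos[pairs$i]
  mean(softplus(d))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Enumerate all pos-neg pairs, or subsample max_pairs of them (uses the
# current RNG stream; callers seed it).
rank_pairs <- function(np, nn, max_pairs) {
  total <- as.double(np) * nn
  if (total <= max_pairs) {
    list(i = rep(seq_len(np), each = nn), j = rep(seq_len(nn), np))
  } else {
    k <- sample.int(total, max_pairs)   # total < 2^31 in practice
    list(i = as.integer((k - 1) %/% nn) + 1L,
         j = as.integer((k - 1) %% nn) + 1L)
  }
}

# Gradient of auc_rank_loss w.r.t. all scores over a given pair set.
rank_grad_from_pairs <- function(s_pos, s_neg, pairs) {
  m <- length(pairs$i)
  sig <- plogis(s_neg[pairs$j] - s_pos[pairs$i])
  d_pos <- numeric(length(s_pos)); d_neg <- numeric(length(s_neg))
  tp <- rowsum(sig, pairs$i)
  d_pos[as.integer(rownames(tp))] <- -tp[, 1]
  tn <- rowsum(sig, pairs$j)
  d_neg[as.integer(rownames(tn))] <- tn[, 1]
  list(d_pos = d_pos / m, d_neg = d_neg / m)
}

# Composite training loss on logits s: focal + lambda * rank; the ranking
# term and its gradient share one pair subsample. Returns loss components
# and gradient w.r.t. logits.
composite_loss <- function(s, y, alpha, gamma, lambda, max_pairs = 1e4) {
  p <- plogis(s)
  fl <- focal_loss(p, y, alpha, gamma)
  g <- focal_loss_grad_logit(p, y, alpha, gamma)
  pos <- which(y == 1); neg <- which(y == 0)
  rl <- 0
  if (lambda > 0 && length(pos) && length(neg)) {
    pairs <- rank_pairs(length(pos), length(neg), max_pairs)
    sp <- s[pos]; sn <- s[neg]
    rl <- mean(softplus(sn[pairs$j] - sp[pairs$i]))
    rg <- rank_grad_from_pairs(sp, sn, pairs)
    g[pos] <- g[pos] + lambda * rg$d_pos
    g[neg] <- g[neg] + lambda * rg$d_neg
  }
  list(loss = fl + lambda * rl, focal = fl, rank = rl, grad = g)
}
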