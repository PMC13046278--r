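# Independent double-precision reference implementations used as oracles.

# Pure-R forward pass of the transformer on one batch (no dropout).
# Mirrors the architecture contract, not the compiled code: written from the
# layer definitions. X: array (B, T, F); S: matrix (B, Fs); params: flat
# vector with the documented layout from param_layout().
ref_transformer_forward <- function(params, cfg, X, S) {
  lay <- iohcast:::param_layout(cfg)
  get_par <- function(name, nr = NULL) {
    r <- lay[lay$name == name, ]
    v <- params[r$offset + seq_len(r$n)]
    if (is.null(nr)) v else matrix(v, nrow = nr)
  }
  B <- dim(X)[1]; T_ <- cfg$seq_len; F_ <- cfg$f_dyn
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d / H
  k <- cfg$conv_kernel; pad <- (k - 1) / 2

  layernorm <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      mu <- mean(r); v <- mean((r - mu)^2)
      (r - mu) / sqrt(v + 1e-5) * g + b
    }))
  }

  logits <- numeric(B)
  for (bi in seq_len(B)) {
    xb <- matrix(X[bi, , ], T_, F_)       # T x F
    # conv1d, same padding
    convW <- get_par("conv_W")
    x <- matrix(0, T_, d)
    for (j in seq_len(k)) {
      Wj <- matrix(convW[(j - 1) * F_ * d + seq_len(F_ * d)], F_, d)
      off <- j - 1 - pad
      for (t in seq_len(T_)) {
        ts <- t + off
        if (ts >= 1 && ts <= T_) x[t, ] <- x[t, ] + xb[ts, ] %*% Wj
      }
    }
    x <- sweep(x, 2, get_par("conv_b"), "+")
    # positional encoding
    for (t in seq_len(T_)) {
      for (i in seq(1, d, by = 2)) {
        ang <- (t - 1) / 10000^((i - 1) / d)
        x[t, i] <- x[t, i] + sin(ang)
        if (i + 1 <= d) x[t, i + 1] <- x[t, i + 1] + cos(ang)
      }
    }
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("l", l, "_")
      xn <- layernorm(x, get_par(paste0(pre, "ln1_g")), get_par(paste0(pre, "ln1_b")))
      Q <- xn %*% get_par(paste0(pre, "Wq"), d)
      Q <- sweep(Q, 2, get_par(paste0(pre, "bq")), "+")
      K <- xn %*% get_par(paste0(pre, "Wk"), d)
      K <- sweep(K, 2, get_par(paste0(pre, "bk")), "+")
      V <- xn %*% get_par(paste0(pre, "Wv"), d)
      V <- sweep(V, 2, get_par(paste0(pre, "bv")), "+")
      AO <- matrix(0, T_, d)
      for (h in seq_len(H)) {
        cols <- (h - 1) * dh + seq_len(dh)
        Sc <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
        P <- t(apply(Sc, 1, function(r) {
          e <- exp(r - max(r)); e / sum(e)
        }))
        AO[, cols] <- P %*% V[, cols, drop = FALSE]
      }
      proj <- AO %*% get_par(paste0(pre, "Wo"), d)
      proj <- sweep(proj, 2, get_par(paste0(pre, "bo")), "+")
      x <- x + proj
      xn2 <- layernorm(x, get_par(paste0(pre, "ln2_g")), get_par(paste0(pre, "ln2_b")))
      H1 <- xn2 %*% get_par(paste0(pre, "W1"), d)
      H1 <- pmax(sweep(H1, 2, get_par(paste0(pre, "b1")), "+"), 0)
      ff <- H1 %*% get_par(paste0(pre, "W2"), cfg$d_ff)
      ff <- sweep(ff, 2, get_par(paste0(pre, "b2")), "+")
      x <- x + ff
    }
    x <- layernorm(x, get_par("lnf_g"), get_par("lnf_b"))
    pooled <- colMeans(x)
    hw <- get_par("head_w")
    logits[bi] <- sum(c(pooled, S[bi, ]) * hw) + get_par("head_b")
  }
  logits
}

# Brute-force IOH event scan: per-minute loop, no vectorized shortcuts.
ref_detect_events <- function(map, threshold, min_duration) {
  below <- !is.na(map) & map < threshold
  events <- list()
  i <- 1
  while (i <= length(map)) {
    if (below[i]) {
      j <- i
      while (j < length(map) && below[j + 1]) j <- j + 1
      if (j - i + 1 >= min_duration) {
        events[[length(events) + 1]] <- c(start = i - 1, end = j - 1)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(events)) {
    return(data.frame(start_min = integer(), end_min = integer()))
  }
  data.frame(start_min = as.integer(vapply(events, `[[`, 0, "start")),
             end_min = as.integer(vapply(events, `[[`, 0, "end")))
}

# Exhaustive per-epoch labeling scan mirroring the written contract.
ref_label_epochs <- function(map, threshold, min_duration, horizon, seq_len,
                             exclude_in_event = TRUE) {
  D <- length(map)
  ev <- ref_detect_events(map, threshold, min_duration)
  out <- list()
  if (D - 1 - horizon < seq_len - 1) {
    return(data.frame(t_end = integer(), label = integer()))
  }
  for (t in seq(seq_len - 1, D - 1 - horizon)) {
    win <- (t + 1):(t + horizon)
    starts_in <- any(ev$start_min %in% win)
    below_in <- any(!is.na(map[win + 1]) & map[win + 1] < threshold)
    label <- if (starts_in) 1L else if (!below_in) 0L else NA_integer_
    if (exclude_in_event && !is.na(map[t + 1]) && map[t + 1] < threshold) {
      label <- NA_integer_
    }
    out[[length(out) + 1]] <- data.frame(t_end = t, label = label)
  }
  if (!length(out)) return(data.frame(t_end = integer(), label = integer()))
  do.call(rbind, out)
}

# Quadratic-time AUC by pair counting, ties 1/2.
ref_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Step-wise average precision by direct accumulation.
ref_average_precision <- function(y, p) {
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  P <- sum(y == 1)
  tp <- 0; ap <- 0; prev_rec <- 0
  groups <- split(seq_along(ps), -ps)
  # iterate distinct scores in descending order
  for (g in groups[order(as.numeric(names(groups)))]) {
    tp <- tp + sum(ys[g] == 1)
    k <- max(g)
    rec <- tp / P
    prec <- tp / k
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Loop-based binning oracle for the expected calibration error.
ref_ece <- function(y, p, n_bins) {
  tot <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins; hi <- b / n_bins
    inb <- if (b == n_bins) p >= lo & p <= hi else p >= lo & p < hi
    if (!any(inb)) next
    tot <- tot + sum(inb) / length(p) * abs(mean(y[inb]) - mean(p[inb]))
  }
  tot
}

# Per-minute loop oracle for the burden area.
ref_burden_area <- function(map, threshold) {
  area <- 0; mins <- 0
  for (m in map) {
    if (!is.na(m) && m <= threshold) {
      area <- area + (threshold - m)
      mins <- mins + 1
    }
  }
  c(area = area, minutes = mins)
}

# Rule-by-rule KDIGO/ADQI reference staging.
ref_stage_aki <- function(days, scr, baseline) {
  keep <- days > 0 & days <= 7 & !is.na(scr)
  if (!any(keep)) return(NA_integer_)
  d <- c(0, days[keep]); v <- c(baseline, scr[keep])
  rise <- FALSE
  for (j in seq_along(d)) {
    for (i in seq_along(d)) {
      if (d[i] <= d[j] && d[j] - d[i] <= 2 && v[j] - v[i] >= 0.3) rise <- TRUE
    }
  }
  ratio <- max(v[-1]) / baseline
  st <- if (ratio >= 3) 3L else if (ratio >= 2) 2L else if (ratio >= 1.5) 1L else 0L
  if (st == 0L && rise) st <- 1L
  if (st >= 1L && max(v[-1]) >= 4.0) st <- 3L
  st
}

ref_stage_akd <- function(days, scr, baseline) {
  keep <- days >= 8 & days <= 90 & !is.na(scr)
  if (!any(keep)) return(0L)
  ratio <- max(scr[keep]) / baseline
  if (ratio >= 3) 3L else if (ratio >= 2) 2L else if (ratio >= 1.5) 1L else 0L
}

# Small helpers shared by tests: a fully observed gridded case.
make_simple_case <- function(D = 40, case_id = "c1", map = NULL, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    case_id = case_id, time_min = 0:(D - 1),
    HR = rnorm(D, 70, 3), PULSE = rnorm(D, 70, 3),
    SBP = rnorm(D, 120, 5), DBP = rnorm(D, 65, 4),
    MAP = if (is.null(map)) rnorm(D, 85, 4) else map,
    NIBP_SYS = rnorm(D, 120, 5), NIBP_DIA = rnorm(D, 65, 4),
    RR = rnorm(D, 14, 1), SPO2 = pmin(100, rnorm(D, 98, 0.5)),
    ETCO2 = rnorm(D, 35, 2), TEMP = rnorm(D, 36.5, 0.1)
  )
}

simple_cases_table <- function(vitals) {
  ids <- unique(vitals$case_id)
  tibble::tibble(case_id = ids, patient_id = paste0("p_", ids),
                 age = 55, sex = 1, asa = 2)
}
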