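# Independent brute-force oracles: every formula re-implemented as explicit
# loops, kept deliberately separate from the package's vectorized paths.

rmat <- function(n, m, sd = 1) matrix(rnorm(n * m, sd = sd), n, m)

oracle_gcn <- function(states, adjacency, weights, bias, relu = TRUE) {
  n <- nrow(states); dout <- ncol(weights)
  out <- matrix(0, n, dout)
  for (i in seq_len(n)) {
    agg <- rep(0, ncol(states))
    for (j in seq_len(n)) agg <- agg + adjacency[i, j] * states[j, ]
    for (k in seq_len(dout)) {
      v <- sum(agg * weights[, k]) + bias[k]
      out[i, k] <- if (relu) max(v, 0) else v
    }
  }
  out
}

oracle_pool_dir <- function(x) {
  d <- dim(x)
  ph <- matrix(0, d[1], d[2]); pw <- matrix(0, d[1], d[3])
  for (c_ in seq_len(d[1])) {
    for (h in seq_len(d[2])) {
      s <- 0
      for (w in seq_len(d[3])) s <- s + x[c_, h, w]
      ph[c_, h] <- s / d[3]
    }
    for (w in seq_len(d[3])) {
      s <- 0
      for (h in seq_len(d[2])) s <- s + x[c_, h, w]
      pw[c_, w] <- s / d[2]
    }
  }
  list(pooled_h = ph, pooled_w = pw)
}

oracle_coord_apply <- function(x, gh, gw) {
  d <- dim(x)
  y <- array(0, d)
  for (c_ in seq_len(d[1]))
    for (i in seq_len(d[2]))
      for (j in seq_len(d[3]))
        y[c_, i, j] <- x[c_, i, j] * gh[c_, i] * gw[c_, j]
  y
}

oracle_descriptor <- function(x) {
  d <- dim(x)
  z <- numeric(d[1])
  for (c_ in seq_len(d[1])) {
    s <- 0
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) s <- s + x[c_, i, j]
    z[c_] <- s / (d[2] * d[3])
  }
  z
}

oracle_softmax_rows <- function(z) {
  out <- z
  for (i in seq_len(nrow(z))) {
    e <- exp(z[i, ] - max(z[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

oracle_cross_attn <- function(fd, fp, params) {
  dk <- ncol(params$wdq)
  qd <- fd %*% params$wdq
  kp <- fp %*% params$wpk
  logits <- matrix(0, nrow(fd), nrow(fp))
  for (i in seq_len(nrow(fd)))
    for (j in seq_len(nrow(fp)))
      logits[i, j] <- sum(qd[i, ] * kp[j, ]) / sqrt(dk)
  attn <- oracle_softmax_rows(logits)
  vp <- fp %*% params$wpv
  z <- matrix(0, nrow(fd), ncol(vp))
  for (i in seq_len(nrow(fd)))
    for (k in seq_len(ncol(vp)))
      z[i, k] <- sum(attn[i, ] * vp[, k])
  list(attn = attn, z = z)
}

oracle_colmax <- function(x) {
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    m <- -Inf
    for (i in seq_len(nrow(x))) if (x[i, j] > m) m <- x[i, j]
    out[j] <- m
  }
  out
}

oracle_bce <- function(y, p, eps = 1e-7) {
  total <- 0
  for (i in seq_along(y)) {
    pi_ <- min(max(p[i], eps), 1 - eps)
    total <- total - (y[i] * log(pi_) + (1 - y[i]) * log(1 - pi_))
  }
  total / length(y)
}

oracle_auroc <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

oracle_auprc <- function(labels, scores) {
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  tp <- 0; ap <- 0; prev_rec <- 0
  for (k in seq_along(ord)) {
    if (labels[ord[k]] == 1) tp <- tp + 1
    prec <- tp / k
    rec <- tp / np
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

oracle_confusion_metrics <- function(labels, scores, thr = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(labels)) {
    pred <- as.numeric(scores[i] >= thr)
    if (pred == 1 && labels[i] == 1) tp <- tp + 1
    if (pred == 1 && labels[i] == 0) fp <- fp + 1
    if (pred == 0 && labels[i] == 0) tn <- tn + 1
    if (pred == 0 && labels[i] == 1) fn <- fn + 1
  }
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(accuracy = acc, f1 = f1, mcc = mcc)
}
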