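# Reverse-mode automatic differentiation on matrices.
#
# All network activations are dense matrices laid out positions x channels.
# A tape records every operation; `ad_backward()` walks it in reverse and
# accumulates gradients into parameter leaves. Constants (pooling matrices,
# masks, neighbor index tables) are passed as plain R objects and never enter
# the tape, which keeps the per-sample node count small.

ad_tape <- function(capacity = 512L, grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", capacity)
  tp$n <- 0L
  tp$g <- grad
  tp
}

ad_new <- function(tp, value, parents = list(), backward = NULL, param = FALSE,
                   cache = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (!tp$g) return(nd)     # inference-only tape: no backward bookkeeping
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  nd$cache <- cache
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

ad_value <- function(x) if (is.environment(x)) x$value else x

ad_acc <- function(nd, g) {
  if (is.environment(nd)) {
    nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  }
  invisible(NULL)
}

# Seed `node` with gradient 1 (scalars) or a supplied gradient and sweep the
# tape backwards. Nodes never reached keep grad NULL.
ad_backward <- function(tp, node, seed = 1) {
  node$grad <- seed
  for (i in seq(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

ad_leaf <- function(tp, value, param = FALSE) ad_new(tp, value, param = param)

# ---- primitive operations ---------------------------------------------------

ad_mm <- function(tp, a, b, ta = FALSE, tb = FALSE) {
  A <- ad_value(a); B <- ad_value(b)
  v <- if (!ta && !tb) A %*% B
  else if (ta && !tb) crossprod(A, B)
  else if (!ta && tb) tcrossprod(A, B)
  else stop("double-transposed product not supported")
  ad_new(tp, v, list(a, b), function(nd) {
    g <- nd$grad
    if (!ta && !tb) {
      ad_acc(a, tcrossprod(g, B)); ad_acc(b, crossprod(A, g))
    } else if (ta && !tb) {
      ad_acc(a, tcrossprod(B, g)); ad_acc(b, A %*% g)
    } else {
      ad_acc(a, g %*% B); ad_acc(b, crossprod(g, A))
    }
  })
}

ad_add <- function(tp, a, b) {
  ad_new(tp, ad_value(a) + ad_value(b), list(a, b), function(nd) {
    ad_acc(a, nd$grad); ad_acc(b, nd$grad)
  })
}

ad_scale <- function(tp, x, s) {
  ad_new(tp, ad_value(x) * s, list(x), function(nd) ad_acc(x, nd$grad * s))
}

ad_mul <- function(tp, a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_new(tp, A * B, list(a, b), function(nd) {
    ad_acc(a, nd$grad * B); ad_acc(b, nd$grad * A)
  })
}

# Multiply by a constant (vector recycled down columns, or full matrix).
ad_mul_const <- function(tp, x, m) {
  ad_new(tp, ad_value(x) * m, list(x), function(nd) ad_acc(x, nd$grad * m))
}

# Broadcast-multiply each row of x (P x C) by a column node w (P x 1).
ad_mul_col <- function(tp, x, w) {
  X <- ad_value(x); wv <- as.vector(ad_value(w))
  ad_new(tp, X * wv, list(x, w), function(nd) {
    ad_acc(x, nd$grad * wv)
    ad_acc(w, matrix(rowSums(nd$grad * X), ncol = 1))
  })
}

ad_relu <- function(tp, x) {
  X <- ad_value(x)
  pos <- X > 0
  ad_new(tp, X * pos, list(x), function(nd) ad_acc(x, nd$grad * pos))
}

ad_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-ad_value(x)))
  ad_new(tp, s, list(x), function(nd) ad_acc(x, nd$grad * s * (1 - s)))
}

# Row-wise softmax with an optional additive mask (plain matrix of 0 /
# -large) applied to the logits before normalization.
ad_softmax_rows <- function(tp, x, add_mask = NULL) {
  Z <- ad_value(x)
  if (!is.null(add_mask)) Z <- Z + add_mask
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)
  S <- E / rowSums(E)
  ad_new(tp, S, list(x), function(nd) {
    g <- nd$grad
    ad_acc(x, S * (g - rowSums(g * S)))
  })
}

# 2-D (or 1-D) convolution expressed through a precomputed neighbor index
# table: nbr is P x K with entries in 1..P or 0 for positions outside the
# map (zero padding). W is a (K*C_in) x C_out node, b a length-C_out node.
ad_conv_nbr <- function(tp, x, w, b, nbr) {
  X <- ad_value(x); Wv <- ad_value(w); bv <- as.vector(ad_value(b))
  P <- nrow(X); C <- ncol(X); K <- ncol(nbr)
  Xpad <- rbind(X, 0)
  idx <- nbr
  idx[idx == 0L] <- P + 1L
  cols <- vector("list", K)
  for (k in seq_len(K)) cols[[k]] <- Xpad[idx[, k], , drop = FALSE]
  Xcol <- do.call(cbind, cols)
  out <- Xcol %*% Wv + matrix(bv, P, length(bv), byrow = TRUE)
  ad_new(tp, out, list(x, w, b), function(nd) {
    g <- nd$grad
    ad_acc(w, crossprod(Xcol, g))
    ad_acc(b, colSums(g))
    dXcol <- tcrossprod(g, Wv)
    dX <- matrix(0, P, C)
    for (k in seq_len(K)) {
      sel <- nbr[, k] > 0L
      if (any(sel)) {
        dX[nbr[sel, k], ] <- dX[nbr[sel, k], , drop = FALSE] +
          dXcol[sel, (k - 1L) * C + seq_len(C), drop = FALSE]
      }
    }
    ad_acc(x, dX)
  })
}

# Row gather (embedding lookup / row slice). idx may repeat.
ad_gather_rows <- function(tp, x, idx) {
  X <- ad_value(x)
  ad_new(tp, X[idx, , drop = FALSE], list(x), function(nd) {
    dX <- matrix(0, nrow(X), ncol(X))
    rs <- rowsum(nd$grad, group = idx)
    dX[as.integer(rownames(rs)), ] <- rs
    ad_acc(x, dX)
  })
}

ad_rbind <- function(tp, a, b) {
  A <- ad_value(a); B <- ad_value(b)
  na <- nrow(A)
  ad_new(tp, rbind(A, B), list(a, b), function(nd) {
    g <- nd$grad
    ad_acc(a, g[seq_len(na), , drop = FALSE])
    ad_acc(b, g[na + seq_len(nrow(B)), , drop = FALSE])
  })
}

ad_cbind_list <- function(tp, lst) {
  vals <- lapply(lst, ad_value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_new(tp, do.call(cbind, vals), lst, function(nd) {
    g <- nd$grad
    for (i in seq_along(lst)) {
      ad_acc(lst[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# Column-wise max over the `valid` rows of x; returns a 1 x C node.
ad_maxpool_rows <- function(tp, x, valid) {
  X <- ad_value(x)
  Xv <- X[valid, , drop = FALSE]
  arg <- valid[max.col(t(Xv), ties.method = "first")]
  v <- matrix(X[cbind(arg, seq_len(ncol(X)))], nrow = 1)
  ad_new(tp, v, list(x), function(nd) {
    dX <- matrix(0, nrow(X), ncol(X))
    dX[cbind(arg, seq_len(ncol(X)))] <- as.vector(nd$grad)
    ad_acc(x, dX)
  })
}

# Numerically stable binary cross-entropy on logits; mean over entries.
ad_bce_logits <- function(tp, z, y) {
  Z <- ad_value(z)
  v <- mean(pmax(Z, 0) - Z * y + log1p(exp(-abs(Z))))
  ad_new(tp, v, list(z), function(nd) {
    p <- 1 / (1 + exp(-Z))
    ad_acc(z, nd$grad * (p - y) / length(Z))
  })
}

# Inverted dropout; draws from the session RNG (seeded by the trainer).
ad_dropout <- function(tp, x, rate) {
  X <- ad_value(x)
  if (rate <= 0) return(x)
  keep <- (matrix(stats::runif(length(X)), nrow(X), ncol(X)) >= rate) / (1 - rate)
  ad_new(tp, X * keep, list(x), function(nd) ad_acc(x, nd$grad * keep))
}

# ---- grouped-channel helpers ------------------------------------------------
# A P x C map whose channels form G contiguous groups of Cg = C/G is
# "stacked" into a (G*P) x Cg matrix (group g occupying rows (g-1)*P + 1..P),
# so grouped 1x1 / 3x3 convolutions and pooling become single matrix
# products with block-structured constants.

ad_stack_groups <- function(tp, x, G) {
  X <- ad_value(x)
  P <- nrow(X); C <- ncol(X); Cg <- C %/% G
  v <- matrix(aperm(array(X, c(P, Cg, G)), c(1, 3, 2)), P * G, Cg)
  ad_new(tp, v, list(x), function(nd) {
    g <- nd$grad
    ad_acc(x, matrix(aperm(array(g, c(P, G, Cg)), c(1, 3, 2)), P, C))
  })
}

ad_unstack_groups <- function(tp, x, G) {
  X <- ad_value(x)
  P <- nrow(X) %/% G; Cg <- ncol(X)
  v <- matrix(aperm(array(X, c(P, G, Cg)), c(1, 3, 2)), P, Cg * G)
  ad_new(tp, v, list(x), function(nd) {
    g <- nd$grad
    ad_acc(x, matrix(aperm(array(g, c(P, Cg, G)), c(1, 3, 2)), P * G, Cg))
  })
}

# Group normalization on a stacked map: independent statistics per group
# over its `valid` rows (all channels pooled), shared per-channel affine.
# Rows outside the valid sets are zeroed.
ad_group_norm_groups <- function(tp, x, gamma, beta, valid_list, eps = 1e-5) {
  X <- ad_value(x)
  gv <- as.vector(ad_value(gamma)); bv <- as.vector(ad_value(beta))
  C <- ncol(X)
  out <- matrix(0, nrow(X), C)
  stats <- vector("list", length(valid_list))
  for (g in seq_along(valid_list)) {
    rows <- valid_list[[g]]
    Xv <- X[rows, , drop = FALSE]
    mu <- mean(Xv); va <- mean((Xv - mu)^2); sd_ <- sqrt(va + eps)
    xh <- (Xv - mu) / sd_
    out[rows, ] <- xh * matrix(gv, length(rows), C, byrow = TRUE) +
      matrix(bv, length(rows), C, byrow = TRUE)
    stats[[g]] <- list(rows = rows, xh = xh, sd = sd_)
  }
  ad_new(tp, out, list(x, gamma, beta), function(nd) {
    g_ <- nd$grad
    dX <- matrix(0, nrow(X), C)
    dg <- numeric(C); db <- numeric(C)
    for (st in stats) {
      gr <- g_[st$rows, , drop = FALSE]
      dg <- dg + colSums(gr * st$xh)
      db <- db + colSums(gr)
      dxhat <- gr * matrix(gv, length(st$rows), C, byrow = TRUE)
      dX[st$rows, ] <- (dxhat - mean(dxhat) - st$xh * mean(dxhat * st$xh)) / st$sd
    }
    ad_acc(x, dX)
    ad_acc(gamma, dg)
    ad_acc(beta, db)
  })
}

# Per-group vector contraction: for each group g, y[(g-1)P + p] =
# sum_j x[(g-1)P + p, j] * d[g, j]. Used for descriptor-map products.
ad_group_rowdot <- function(tp, x, d, G) {
  X <- ad_value(x); D <- ad_value(d)
  P <- nrow(X) %/% G
  Dexp <- D[rep(seq_len(G), each = P), , drop = FALSE]
  v <- matrix(rowSums(X * Dexp), ncol = 1)
  ad_new(tp, v, list(x, d), function(nd) {
    g <- as.vector(nd$grad)
    ad_acc(x, Dexp * g)
    ad_acc(d, rowsum(X * g, group = rep(seq_len(G), each = P)))
  })
}

# Fused affine map: x %*% w + bias (bias recycled over rows).
ad_affine <- function(tp, x, w, b) {
  X <- ad_value(x); W <- ad_value(w); bv <- as.vector(ad_value(b))
  v <- X %*% W
  v <- v + matrix(bv, nrow(v), length(bv), byrow = TRUE)
  ad_new(tp, v, list(x, w, b), function(nd) {
    g <- nd$grad
    ad_acc(x, tcrossprod(g, W))
    ad_acc(w, crossprod(X, g))
    ad_acc(b, colSums(g))
  })
}

# Fused ReLU + row-mask (mask is a plain 0/1 vector recycled down columns).
ad_relu_mask <- function(tp, x, mask) {
  X <- ad_value(x)
  keep <- (X > 0) * mask
  ad_new(tp, X * keep, list(x), function(nd) ad_acc(x, nd$grad * keep))
}
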