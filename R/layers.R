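# Numeric (non-differentiable) forms of the network's building blocks. These
# are the equation-level operations exposed to users and tests; the trainable
# model mirrors them on the autodiff tape (R/model.R), and consistency
# between the two paths is asserted in the test suite.

#' One graph-convolution layer
#'
#' Computes `H' = sigma(A %*% H %*% W + b)`, the neighborhood aggregation of
#' node states through a self-loop-augmented (optionally degree-normalized)
#' adjacency.
#'
#' @param states `N x D_in` node state matrix.
#' @param adjacency `N x N` adjacency (with self-loops on real atoms).
#' @param weights `D_in x D_out` weight matrix.
#' @param bias Length-`D_out` bias vector.
#' @param activation `"relu"` or `"identity"`.
#' @param mask Optional 0/1 vector of real atoms; padding rows are re-zeroed
#'   after the update.
#' @return `N x D_out` matrix of updated node states.
#' @export
gcn_layer <- function(states, adjacency, weights, bias = numeric(ncol(weights)),
                      activation = c("relu", "identity"), mask = NULL) {
  activation <- match.arg(activation)
  if (ncol(adjacency) != nrow(states)) stop("adjacency/state dimension mismatch")
  if (ncol(states) != nrow(weights)) stop("state/weight dimension mismatch")
  z <- adjacency %*% states %*% weights
  z <- z + matrix(bias, nrow(z), length(bias), byrow = TRUE)
  if (activation == "relu") z <- pmax(z, 0)
  if (!is.null(mask)) z <- z * mask
  z
}

#' Directional average pooling
#'
#' Pools a `C x H x W` map along the width direction (per-row means,
#' producing `C x H`) and along the height direction (per-column means,
#' `C x W`). With a validity mask, means are taken over valid cells only and
#' fully-masked rows/columns yield 0.
#'
#' @param x Numeric array with dimensions `(C, H, W)`.
#' @param mask Optional `H x W` 0/1 matrix of valid cells.
#' @return List with `pooled_h` (`C x H`) and `pooled_w` (`C x W`).
#' @export
directional_pool <- function(x, mask = NULL) {
  stopifnot(length(dim(x)) == 3)
  d <- dim(x)
  if (is.null(mask)) mask <- matrix(1, d[2], d[3])
  mh <- rowSums(mask)
  mw <- colSums(mask)
  pooled_h <- matrix(0, d[1], d[2])
  pooled_w <- matrix(0, d[1], d[3])
  for (c_ in seq_len(d[1])) {
    xc <- x[c_, , , drop = TRUE]
    if (is.null(dim(xc))) xc <- matrix(xc, d[2], d[3])
    num_h <- rowSums(xc * mask)
    num_w <- colSums(xc * mask)
    pooled_h[c_, mh > 0] <- num_h[mh > 0] / mh[mh > 0]
    pooled_w[c_, mw > 0] <- num_w[mw > 0] / mw[mw > 0]
  }
  list(pooled_h = pooled_h, pooled_w = pooled_w)
}

#' Coordinate-attention gates
#'
#' Builds the directional gates from a spatial map: directional pooling,
#' concatenation, a shared channel-reducing 1x1 transform with ReLU, then two
#' separate 1x1 transforms and a sigmoid (one per direction).
#'
#' @param x `(C, H, W)` array.
#' @param params List with `w1` (`C/r x C`), `b1`, `wh` (`C x C/r`), `bh`,
#'   `ww` (`C x C/r`), `bw`; see [init_ca_params()].
#' @param mask Optional `H x W` validity mask used by the pooling step.
#' @return List with `gate_h` (`C x H`) and `gate_w` (`C x W`), entries in
#'   (0, 1).
#' @export
coordinate_gates <- function(x, params, mask = NULL) {
  p <- directional_pool(x, mask)
  cat_ <- cbind(p$pooled_h, p$pooled_w)        # C x (H+W)
  f <- pmax(params$w1 %*% cat_ + params$b1, 0) # C/r x (H+W)
  H <- ncol(p$pooled_h)
  fh <- f[, seq_len(H), drop = FALSE]
  fw <- f[, -seq_len(H), drop = FALSE]
  list(gate_h = sigmoid(params$wh %*% fh + params$bh),
       gate_w = sigmoid(params$ww %*% fw + params$bw))
}

#' Apply coordinate attention
#'
#' Re-weights every cell of a spatial map by the product of its row gate and
#' column gate: `y[c,i,j] = x[c,i,j] * gate_h[c,i] * gate_w[c,j]`.
#'
#' @param x `(C, H, W)` array.
#' @param gates List with `gate_h` (`C x H`) and `gate_w` (`C x W`), e.g.
#'   from [coordinate_gates()].
#' @return Array with the same dimensions as `x`.
#' @export
coordinate_attention <- function(x, gates) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (!all(dim(gates$gate_h) == d[c(1, 2)]) ||
      !all(dim(gates$gate_w) == d[c(1, 3)])) {
    stop("gate dimensions do not match the spatial map")
  }
  y <- x
  for (c_ in seq_len(d[1])) {
    y[c_, , ] <- x[c_, , ] * outer(gates$gate_h[c_, ], gates$gate_w[c_, ])
  }
  y
}

#' Split a map into channel groups
#'
#' Contiguous, lossless split of a `(C, H, W)` map into `G` groups of
#' `C / G` channels each.
#'
#' @param x `(C, H, W)` array.
#' @param G Number of groups; `C` must be divisible by `G`.
#' @return List of `G` arrays of dimension `(C/G, H, W)`.
#' @export
split_groups <- function(x, G) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (d[1] %% G != 0) {
    stop("channel count ", d[1], " not divisible by G = ", G)
  }
  cg <- d[1] %/% G
  lapply(seq_len(G), function(g) {
    x[(g - 1L) * cg + seq_len(cg), , , drop = FALSE]
  })
}

#' Per-channel global descriptor
#'
#' The spatial mean of each channel, `Z_c = mean_{i,j} X_c(i, j)` (over valid
#' cells when a mask is given).
#'
#' @param x `(C, H, W)` array.
#' @param mask Optional `H x W` validity mask.
#' @return Numeric vector of length `C`.
#' @export
global_descriptor <- function(x, mask = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (is.null(mask)) mask <- matrix(1, d[2], d[3])
  denom <- sum(mask)
  vapply(seq_len(d[1]), function(c_) {
    xc <- x[c_, , ]
    sum(xc * mask) / denom
  }, 0)
}

#' Cross-attention between drug and protein features
#'
#' Scaled dot-product attention in both directions: the drug features query
#' the protein features and vice versa. Attention logits at padded key
#' positions are masked to -Inf before the softmax, so every valid attention
#' row sums to 1 over valid keys. The attention weights aggregate the
#' opposite modality's value projection, mapping the result back to the
#' querying modality's shape.
#'
#' @param f_d `N_d x D` drug feature matrix.
#' @param f_p `theta_p x D` protein feature matrix.
#' @param params List of projections `wdq`, `wdk`, `wdv`, `wpq`, `wpk`,
#'   `wpv` (`D x d_k` for queries/keys, `D x D` for values).
#' @param mask_d,mask_p 0/1 vectors marking valid rows of `f_d` / `f_p`.
#' @return List with `z_d` (`N_d x D`), `z_p` (`theta_p x D`), and the
#'   attention matrices `attn_d` (`N_d x theta_p`), `attn_p`
#'   (`theta_p x N_d`).
#' @export
cross_attend <- function(f_d, f_p, params, mask_d = NULL, mask_p = NULL) {
  if (ncol(f_d) != ncol(f_p)) stop("feature widths differ between modalities")
  if (is.null(mask_d)) mask_d <- rep(1, nrow(f_d))
  if (is.null(mask_p)) mask_p <- rep(1, nrow(f_p))
  if (!any(mask_d > 0) || !any(mask_p > 0)) stop("all key positions are masked")
  dk <- ncol(params$wdq)
  qd <- f_d %*% params$wdq
  kp <- f_p %*% params$wpk
  qp <- f_p %*% params$wpq
  kd <- f_d %*% params$wdk
  attn_d <- masked_softmax_rows(tcrossprod(qd, kp) / sqrt(dk), mask_p)
  attn_p <- masked_softmax_rows(tcrossprod(qp, kd) / sqrt(dk), mask_d)
  list(z_d = attn_d %*% (f_p %*% params$wpv),
       z_p = attn_p %*% (f_d %*% params$wdv),
       attn_d = attn_d, attn_p = attn_p)
}

masked_softmax_rows <- function(logits, key_mask) {
  logits[, key_mask == 0] <- -Inf
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e[is.na(e)] <- 0
  e / rowSums(e)
}

#' Equal-weight residual mix
#'
#' `0.5 * Z + 0.5 * F`: the attention output and the original features
#' contribute equally, so forcing the attention output to zero halves the
#' representation.
#'
#' @param z,f Matrices of identical shape.
#' @return Their elementwise average.
#' @export
residual_mix <- function(z, f) {
  if (!all(dim(z) == dim(f))) stop("residual mix requires equal shapes")
  0.5 * z + 0.5 * f
}

#' Global max-pool and concatenate
#'
#' Per-dimension maxima of the drug and protein representations over valid
#' rows only, concatenated in (drug, protein) order.
#'
#' @param d_f `N_d x D` mixed drug representation.
#' @param p_f `theta_p x D` mixed protein representation.
#' @param mask_d,mask_p 0/1 row-validity vectors.
#' @return Numeric vector of length `2 * D`.
#' @export
pool_and_concat <- function(d_f, p_f, mask_d = NULL, mask_p = NULL) {
  if (is.null(mask_d)) mask_d <- rep(1, nrow(d_f))
  if (is.null(mask_p)) mask_p <- rep(1, nrow(p_f))
  if (!any(mask_d > 0) || !any(mask_p > 0)) stop("zero valid rows to pool")
  c(apply(d_f[mask_d > 0, , drop = FALSE], 2, max),
    apply(p_f[mask_p > 0, , drop = FALSE], 2, max))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Prediction head
#'
#' A multilayer perceptron on the fused representation whose final unit is
#' `p = sigmoid(W f + b)`. Hidden layers use ReLU; dropout is applied only
#' during training (rate 0 here, the numeric form is deterministic).
#'
#' @param f Fused feature vector.
#' @param head List of layers, each `list(w, b)`; all but the last are
#'   hidden layers.
#' @return Probability in (0, 1).
#' @export
predict_head <- function(f, head) {
  h <- matrix(f, nrow = 1)
  nl <- length(head)
  for (i in seq_len(nl - 1L)) {
    h <- pmax(h %*% head[[i]]$w +
                matrix(head[[i]]$b, 1, length(head[[i]]$b), byrow = TRUE), 0)
  }
  if (ncol(h) != nrow(head[[nl]]$w)) stop("head dimension mismatch")
  as.numeric(sigmoid(h %*% head[[nl]]$w + head[[nl]]$b))
}

#' Binary cross-entropy loss
#'
#' Mean binary cross-entropy over a batch; probabilities are clipped into
#' `(eps, 1 - eps)` before the logs.
#'
#' @param labels 0/1 vector.
#' @param probabilities Predicted probabilities, same length.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
bce_loss <- function(labels, probabilities, eps = 1e-7) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(labels) != length(probabilities)) stop("length mismatch")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
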