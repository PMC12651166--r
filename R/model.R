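# Assembles the full predictor on the autodiff tape: drug branch (GCN x3 +
# multi-scale fusion on a 2-D node grid), protein branch (embedding ->
# optional gated 1-D convolutions -> coordinate attention -> multi-scale
# fusion), cross-attention interaction fusion, and the MLP head. Ablation
# modes rewire this graph; they never touch data handling.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

fusion_param_names <- function(prefix) {
  paste0(prefix, c("_hw_w", "_hw_b", "_conv_w", "_conv_b", "_gn_g", "_gn_b"))
}

init_fusion_params <- function(cg) {
  list(hw_w = glorot(cg, cg), hw_b = matrix(0, 1, cg),
       conv_w = glorot(9L * cg, cg), conv_b = matrix(0, 1, cg),
       gn_g = matrix(1, 1, cg), gn_b = matrix(0, 1, cg))
}

#' Initialize coordinate-attention parameters
#'
#' Glorot-uniform weights for the shared channel-reducing 1x1 transform and
#' the two directional 1x1 transforms of coordinate attention, in the
#' `(C, H, W)`-array convention used by [coordinate_gates()].
#'
#' @param C Channel count.
#' @param r Reduction ratio of the shared transform.
#' @return List with `w1`, `b1`, `wh`, `bh`, `ww`, `bw`.
#' @export
init_ca_params <- function(C, r = 8L) {
  cr <- max(1L, C %/% r)
  list(w1 = glorot(cr, C), b1 = numeric(cr),
       wh = glorot(C, cr), bh = numeric(C),
       ww = glorot(C, cr), bw = numeric(C))
}

# Full parameter set for a configuration; only parameters reachable in the
# configured ablation mode are created.
init_params <- function(cfg) {
  D <- cfg$d_model; dk <- cfg$d_k
  cr <- max(1L, D %/% cfg$ca_reduction)
  th <- list(
    gcn1_w = glorot(ATOM_FEATURE_DIM, D), gcn1_b = matrix(0, 1, D),
    gcn2_w = glorot(D, D), gcn2_b = matrix(0, 1, D),
    gcn3_w = glorot(D, D), gcn3_b = matrix(0, 1, D),
    emb = glorot(22L, D)
  )
  if (cfg$gated_conv) {
    for (l in seq_len(cfg$gated_conv_depth)) {
      th[[paste0("gc", l, "_wa")]] <- glorot(3L * D, D)
      th[[paste0("gc", l, "_ba")]] <- matrix(0, 1, D)
      th[[paste0("gc", l, "_wg")]] <- glorot(3L * D, D)
      th[[paste0("gc", l, "_bg")]] <- matrix(0, 1, D)
    }
  }
  if (cfg$ablation == "Noco") {
    th$noco_w <- glorot(D, D)
    th$noco_b <- matrix(0, 1, D)
  } else {
    th$ca_w1 <- glorot(D, cr); th$ca_b1 <- matrix(0, 1, cr)
    th$ca_wh <- glorot(cr, D); th$ca_bh <- matrix(0, 1, D)
    th$ca_ww <- glorot(cr, D); th$ca_bw <- matrix(0, 1, D)
  }
  if (cfg$ablation != "single") {
    fd <- init_fusion_params(D %/% cfg$groups_drug)
    names(fd) <- fusion_param_names("dfuse")
    fp <- init_fusion_params(D %/% cfg$groups_protein)
    names(fp) <- fusion_param_names("pfuse")
    th <- c(th, fd, fp)
  }
  if (cfg$ablation != "NoCross") {
    th$x_wdq <- glorot(D, dk); th$x_wdk <- glorot(D, dk)
    th$x_wpq <- glorot(D, dk); th$x_wpk <- glorot(D, dk)
    th$x_wdv <- glorot(D, D); th$x_wpv <- glorot(D, D)
  }
  dims <- c(2L * D, cfg$head_dims, 1L)
  for (i in seq_len(length(dims) - 1L)) {
    th[[paste0("head", i, "_w")]] <- glorot(dims[i], dims[i + 1L])
    th[[paste0("head", i, "_b")]] <- matrix(0, 1, dims[i + 1L])
  }
  th
}

# Constant spatial structures for a grid with `n_valid` leading valid
# positions, shared across samples and cached by key.
.struct_cache <- new.env(parent = emptyenv())

grid_structures <- function(h, w, n_valid, G) {
  key <- paste(h, w, n_valid, G, sep = "_")
  hit <- .struct_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- h * w
  mask <- c(rep(1, n_valid), rep(0, P - n_valid))
  valid <- seq_len(n_valid)
  Ph <- pool_rows_matrix(h, w, mask)
  Pw <- pool_cols_matrix(h, w, mask)
  Eh <- expand_rows_matrix(h, w)
  Ew <- expand_cols_matrix(h, w)
  nbr <- neighbors_3x3(h, w)
  IG <- diag(G)
  nbr_st <- do.call(rbind, lapply(seq_len(G), function(g) {
    nb <- nbr
    nb[nb > 0L] <- nb[nb > 0L] + (g - 1L) * P
    nb
  }))
  desc <- matrix(0, G, G * P)
  for (g in seq_len(G)) desc[g, (g - 1L) * P + valid] <- 1 / n_valid
  st <- list(
    h = h, w = w, P = P, G = G, mask = mask, valid = valid,
    Ph = Ph, Pw = Pw, Eh = Eh, Ew = Ew, nbr = nbr,
    Ph_k = kronecker(IG, Ph), Pw_k = kronecker(IG, Pw),
    Eh_k = kronecker(IG, Eh), Ew_k = kronecker(IG, Ew),
    nbr_st = nbr_st, desc = desc,
    valid_list = lapply(seq_len(G), function(g) (g - 1L) * P + valid),
    nbr1d = neighbors_1d3(P)
  )
  .struct_cache[[key]] <- st
  st
}

# Multi-scale fusion block on the tape: input x is a P x C node; returns a
# P x C node. Parameters are shared across the G channel groups.
tape_fusion <- function(tp, x, th, prefix, st) {
  G <- st$G
  xs <- ad_stack_groups(tp, x, G)
  ph <- ad_mm(tp, st$Ph_k, xs)
  pw <- ad_mm(tp, st$Pw_k, xs)
  hw <- ad_affine(tp, ad_rbind(tp, ph, pw), th[[paste0(prefix, "_hw_w")]],
                  th[[paste0(prefix, "_hw_b")]])
  nh <- G * st$h
  gh <- ad_sigmoid(tp, ad_gather_rows(tp, hw, seq_len(nh)))
  gw <- ad_sigmoid(tp, ad_gather_rows(tp, hw, nh + seq_len(G * st$w)))
  x1 <- ad_mul(tp, ad_mul(tp, xs, ad_mm(tp, st$Eh_k, gh)),
               ad_mm(tp, st$Ew_k, gw))
  x1 <- ad_group_norm_groups(tp, x1, th[[paste0(prefix, "_gn_g")]],
                             th[[paste0(prefix, "_gn_b")]], st$valid_list)
  x2 <- ad_conv_nbr(tp, xs, th[[paste0(prefix, "_conv_w")]],
                    th[[paste0(prefix, "_conv_b")]], st$nbr_st)
  d1 <- ad_softmax_rows(tp, ad_mm(tp, st$desc, x1))
  d2 <- ad_softmax_rows(tp, ad_mm(tp, st$desc, x2))
  y1 <- ad_group_rowdot(tp, x2, d1, G)
  y2 <- ad_group_rowdot(tp, x1, d2, G)
  wgt <- ad_sigmoid(tp, ad_add(tp, y1, y2))
  ad_unstack_groups(tp, ad_mul_col(tp, xs, wgt), G)
}

# Coordinate attention block on the tape (full channel width).
tape_coord_attention <- function(tp, x, th, st) {
  ph <- ad_mm(tp, st$Ph, x)
  pw <- ad_mm(tp, st$Pw, x)
  f <- ad_relu(tp, ad_affine(tp, ad_rbind(tp, ph, pw), th$ca_w1, th$ca_b1))
  fh <- ad_gather_rows(tp, f, seq_len(st$h))
  fw <- ad_gather_rows(tp, f, st$h + seq_len(st$w))
  gh <- ad_sigmoid(tp, ad_affine(tp, fh, th$ca_wh, th$ca_bh))
  gw <- ad_sigmoid(tp, ad_affine(tp, fw, th$ca_ww, th$ca_bw))
  ad_mul(tp, ad_mul(tp, x, ad_mm(tp, st$Eh, gh)), ad_mm(tp, st$Ew, gw))
}

# Drug branch: three GCN layers on the (normalized) self-loop adjacency,
# masked after every layer, then multi-scale fusion on the node grid.
tape_drug_branch <- function(tp, th, prep, cfg) {
  std <- prep$std
  h <- ad_relu_mask(tp, ad_affine(tp, prep$ax, th$gcn1_w, th$gcn1_b), std$mask)
  h <- ad_relu_mask(tp, ad_affine(tp, ad_mm(tp, prep$adj, h), th$gcn2_w,
                                  th$gcn2_b), std$mask)
  f_d <- ad_relu_mask(tp, ad_affine(tp, ad_mm(tp, prep$adj, h), th$gcn3_w,
                                    th$gcn3_b), std$mask)
  if (cfg$ablation != "single") f_d <- tape_fusion(tp, f_d, th, "dfuse", std)
  f_d
}

# Protein branch: embedding lookup (pad rows forced to zero), optional gated
# 1-D convolutions, coordinate attention (or its linear replacement in the
# Noco variant), then multi-scale fusion.
tape_protein_branch <- function(tp, th, prep, cfg) {
  stp <- prep$stp
  x <- ad_gather_rows(tp, th$emb, prep$tokens)
  x <- ad_mul_const(tp, x, stp$mask)
  if (cfg$gated_conv) {
    for (l in seq_len(cfg$gated_conv_depth)) {
      a <- ad_conv_nbr(tp, x, th[[paste0("gc", l, "_wa")]],
                       th[[paste0("gc", l, "_ba")]], stp$nbr1d)
      g <- ad_sigmoid(tp, ad_conv_nbr(tp, x, th[[paste0("gc", l, "_wg")]],
                                      th[[paste0("gc", l, "_bg")]], stp$nbr1d))
      x <- ad_mul_const(tp, ad_mul(tp, a, g), stp$mask)
    }
  }
  if (cfg$ablation == "Noco") {
    x <- ad_affine(tp, x, th$noco_w, th$noco_b)
  } else {
    x <- tape_coord_attention(tp, x, th, stp)
  }
  x <- ad_mul_const(tp, x, stp$mask)
  if (cfg$ablation != "single") x <- tape_fusion(tp, x, th, "pfuse", stp)
  x
}

# Full forward pass for one prepared sample. Returns nodes of interest.
forward_sample <- function(tp, th, prep, cfg, training = FALSE) {
  std <- prep$std; stp <- prep$stp
  f_d <- tape_drug_branch(tp, th, prep, cfg)
  f_p <- tape_protein_branch(tp, th, prep, cfg)
  # interaction fusion
  z_p <- NULL
  if (cfg$ablation == "NoCross") {
    d_f <- f_d
    p_f <- f_p
  } else {
    qd <- ad_mm(tp, f_d, th$x_wdq)
    kp <- ad_mm(tp, f_p, th$x_wpk)
    vp <- ad_mm(tp, f_p, th$x_wpv)
    qp <- ad_mm(tp, f_p, th$x_wpq)
    kd <- ad_mm(tp, f_d, th$x_wdk)
    vd <- ad_mm(tp, f_d, th$x_wdv)
    sc <- 1 / sqrt(cfg$d_k)
    attn_d <- ad_softmax_rows(tp, ad_scale(tp, ad_mm(tp, qd, kp, tb = TRUE), sc),
                              add_mask = prep$keymask_p)
    attn_p <- ad_softmax_rows(tp, ad_scale(tp, ad_mm(tp, qp, kd, tb = TRUE), sc),
                              add_mask = prep$keymask_d)
    z_d <- ad_mm(tp, attn_d, vp)
    z_p <- ad_mm(tp, attn_p, vd)
    d_f <- ad_add(tp, ad_scale(tp, z_d, 0.5), ad_scale(tp, f_d, 0.5))
    p_f <- ad_add(tp, ad_scale(tp, z_p, 0.5), ad_scale(tp, f_p, 0.5))
  }
  f <- ad_cbind_list(tp, list(ad_maxpool_rows(tp, d_f, std$valid),
                              ad_maxpool_rows(tp, p_f, stp$valid)))
  nh <- length(cfg$head_dims)
  for (i in seq_len(nh)) {
    f <- ad_relu(tp, ad_affine(tp, f, th[[paste0("head", i, "_w")]],
                               th[[paste0("head", i, "_b")]]))
    if (training && cfg$dropout > 0) f <- ad_dropout(tp, f, cfg$dropout)
  }
  logit <- ad_affine(tp, f, th[[paste0("head", nh + 1L, "_w")]],
                     th[[paste0("head", nh + 1L, "_b")]])
  list(logit = logit, f_d = f_d, f_p = f_p, d_f = d_f, p_f = p_f, z_p = z_p)
}

# Featurize + precompute the constant per-sample inputs of the forward pass.
prepare_sample <- function(graph, tokens_enc, cfg) {
  gd <- grid_dims(cfg$n_d, cfg$grid_w_drug)
  gp <- grid_dims(cfg$theta_p, cfg$grid_w_protein)
  pd <- gd["h"] * gd["w"]
  pp <- gp["h"] * gp["w"]
  std <- grid_structures(gd["h"], gd["w"], graph$n_atoms, cfg$groups_drug)
  stp <- grid_structures(gp["h"], gp["w"], tokens_enc$length, cfg$groups_protein)
  adj <- matrix(0, pd, pd)
  nd <- nrow(graph$adjacency)
  adj[seq_len(nd), seq_len(nd)] <- graph$adjacency
  if (cfg$normalize_adjacency) adj <- normalize_adjacency(adj)
  md <- matrix(0, pd, ATOM_FEATURE_DIM)
  md[seq_len(nd), ] <- graph$node_features
  tokens <- c(tokens_enc$tokens, rep(AA_PAD, pp - length(tokens_enc$tokens)))
  list(adj = adj, ax = adj %*% md, tokens = tokens,
       std = std, stp = stp,
       keymask_p = matrix(ifelse(stp$mask == 0, -1e30, 0), pd, pp, byrow = TRUE),
       keymask_d = matrix(ifelse(std$mask == 0, -1e30, 0), pp, pd, byrow = TRUE))
}

prepare_records <- function(records, cfg, cache = NULL, verbose = FALSE) {
  graphs <- featurize_drugs(records$smiles, cfg$n_d, cache = cache)
  toks <- lapply(records$sequence, tokenize_sequence, theta_p = cfg$theta_p)
  lapply(seq_len(nrow(records)), function(i) {
    p <- prepare_sample(graphs[[i]], toks[[i]], cfg)
    p$label <- records$label[i]
    p
  })
}

# Forward pass without gradient bookkeeping reuse: returns the predicted
# probability for one prepared sample under parameter list `theta`.
predict_prepared <- function(theta, preps, cfg, capture = FALSE) {
  out <- numeric(length(preps))
  captured <- if (capture) vector("list", length(preps)) else NULL
  for (i in seq_along(preps)) {
    tp <- ad_tape(0L, grad = FALSE)
    nodes <- forward_sample(tp, theta, preps[[i]], cfg, training = FALSE)
    out[i] <- sigmoid(ad_value(nodes$logit)[1, 1])
    if (capture) {
      captured[[i]] <- list(p_f = ad_value(nodes$p_f),
                            f_p = ad_value(nodes$f_p),
                            f_d = ad_value(nodes$f_d),
                            z_p = if (is.null(nodes$z_p)) NULL else ad_value(nodes$z_p))
    }
  }
  if (capture) attr(out, "captured") <- captured
  out
}
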