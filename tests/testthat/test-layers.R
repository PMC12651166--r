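# Equation-level operations checked against hand computations and
# brute-force loop oracles.

test_that("graph convolution reproduces hand-computed node updates", {
  # identity layer on a single-node graph
  x <- matrix(2, 1, 3)
  out <- gcn_layer(x, matrix(1, 1, 1), diag(3), activation = "identity")
  expect_equal(out, x)
  # 3-node path with self-loops, unit features, identity weights:
  # node states become degree + 1 = [2, 3, 2]
  adj <- matrix(c(1, 1, 0,
                  1, 1, 1,
                  0, 1, 1), 3, 3, byrow = TRUE)
  h <- matrix(1, 3, 2)
  out <- gcn_layer(h, adj, diag(2), activation = "identity")
  expect_equal(out[, 1], c(2, 3, 2))
  expect_equal(out[, 2], c(2, 3, 2))
  # ReLU output is nonnegative
  set.seed(1)
  out2 <- gcn_layer(rmat(5, 4), diag(5), rmat(4, 3), rnorm(3))
  expect_true(all(out2 >= 0))
})

test_that("graph convolution matches the loop oracle on random instances", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(2:7, 1); din <- sample(2:5, 1); dout <- sample(2:5, 1)
    adj <- matrix(rbinom(n * n, 1, 0.4), n, n)
    adj <- 1 * ((adj + t(adj)) > 0)
    diag(adj) <- 1
    h <- rmat(n, din)
    w <- rmat(din, dout)
    b <- rnorm(dout)
    expect_equal(gcn_layer(h, adj, w, b),
                 oracle_gcn(h, adj, w, b), tolerance = 1e-10)
  }
})

test_that("three stacked layers equal sequential composition, and A = I decouples nodes", {
  set.seed(3)
  adj <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  h0 <- rmat(3, 4)
  ws <- list(rmat(4, 4), rmat(4, 4), rmat(4, 4))
  bs <- list(rnorm(4), rnorm(4), rnorm(4))
  h <- h0
  for (l in 1:3) h <- gcn_layer(h, adj, ws[[l]], bs[[l]])
  hh <- gcn_layer(gcn_layer(gcn_layer(h0, adj, ws[[1]], bs[[1]]),
                            adj, ws[[2]], bs[[2]]), adj, ws[[3]], bs[[3]])
  expect_identical(h, hh)
  # with identity adjacency each node evolves independently
  full <- gcn_layer(h0, diag(3), ws[[1]], bs[[1]])
  for (i in 1:3) {
    solo <- gcn_layer(h0[i, , drop = FALSE], matrix(1, 1, 1), ws[[1]], bs[[1]])
    expect_equal(full[i, ], solo[1, ])
  }
})

test_that("directional pooling matches hand means and a nested-loop oracle", {
  x <- array(0, c(1, 2, 2))
  x[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  p <- directional_pool(x)
  expect_equal(p$pooled_h[1, ], c(1.5, 3.5))
  expect_equal(p$pooled_w[1, ], c(2, 3))
  # constant map pools to the constant
  k <- array(4.2, c(3, 2, 5))
  pk <- directional_pool(k)
  expect_true(all(abs(pk$pooled_h - 4.2) < 1e-12))
  expect_true(all(abs(pk$pooled_w - 4.2) < 1e-12))
  set.seed(4)
  for (rep in 1:20) {
    d <- c(sample(1:4, 1), sample(1:5, 1), sample(1:5, 1))
    x <- array(rnorm(prod(d)), d)
    o <- oracle_pool_dir(x)
    p <- directional_pool(x)
    expect_equal(p$pooled_h, o$pooled_h, tolerance = 1e-12)
    expect_equal(p$pooled_w, o$pooled_w, tolerance = 1e-12)
  }
})

test_that("masked pooling ignores padded cells entirely", {
  set.seed(5)
  x <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  mask <- matrix(1, 3, 4)
  base <- directional_pool(x, mask)
  # double the width with masked garbage
  x2 <- array(rnorm(2 * 3 * 8), c(2, 3, 8))
  x2[, , 1:4] <- x
  mask2 <- cbind(mask, matrix(0, 3, 4))
  ext <- directional_pool(x2, mask2)
  expect_equal(ext$pooled_h, base$pooled_h)
  expect_equal(ext$pooled_w[, 1:4], base$pooled_w)
  expect_true(all(ext$pooled_w[, 5:8] == 0))   # fully-masked columns give 0
})

test_that("coordinate attention is the per-cell gate product", {
  set.seed(6)
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  ones <- list(gate_h = matrix(1, 3, 4), gate_w = matrix(1, 3, 5))
  expect_equal(coordinate_attention(x, ones), x)
  zeros <- list(gate_h = matrix(0, 3, 4), gate_w = matrix(0, 3, 5))
  expect_true(all(coordinate_attention(x, zeros) == 0))
  for (rep in 1:20) {
    gh <- matrix(runif(12), 3, 4)
    gw <- matrix(runif(15), 3, 5)
    expect_equal(coordinate_attention(x, list(gate_h = gh, gate_w = gw)),
                 oracle_coord_apply(x, gh, gw), tolerance = 1e-12)
  }
  expect_error(coordinate_attention(x, list(gate_h = matrix(1, 2, 4),
                                            gate_w = matrix(1, 3, 5))),
               "dimensions")
})

test_that("computed gates lie strictly in (0,1) and attenuate the map", {
  set.seed(7)
  for (rep in 1:10) {
    C <- 8; H <- sample(3:5, 1); W <- sample(3:5, 1)
    x <- array(rnorm(C * H * W, sd = 2), c(C, H, W))
    pars <- init_ca_params(C, r = 4)
    g <- coordinate_gates(x, pars)
    expect_true(all(g$gate_h > 0 & g$gate_h < 1))
    expect_true(all(g$gate_w > 0 & g$gate_w < 1))
    y <- coordinate_attention(x, g)
    expect_true(all(abs(y) <= abs(x)))
  }
})

test_that("coordinate attention is sensitive to residue order", {
  # permuting residues along the sequence axis (before the 2-D reshape)
  # regroups the pooling rows and columns, so the output is NOT the same
  # permutation of the unpermuted output: the block is position-aware,
  # unlike purely channel-wise attention
  ns <- asNamespace("dtifuse")
  set.seed(8)
  cfg <- tiny_config()
  theta <- ns$init_params(cfg)
  st <- ns$grid_structures(4L, 4L, 16L, cfg$groups_protein)
  x <- rmat(16, cfg$d_model)
  perm <- sample(16)
  run <- function(z) {
    tp <- ns$ad_tape(0L, grad = FALSE)
    ns$ad_value(ns$tape_coord_attention(tp, z, theta, st))
  }
  y <- run(x)
  y_perm <- run(x[perm, ])
  expect_gt(max(abs(y_perm - y[perm, ])), 1e-6)
})

test_that("group splitting is contiguous and lossless", {
  set.seed(9)
  x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  expect_equal(split_groups(x, 1)[[1]], x)
  g2 <- split_groups(x, 2)
  expect_equal(g2[[1]][1, , ], x[1, , ])
  expect_equal(g2[[1]][2, , ], x[2, , ])
  expect_equal(g2[[2]][1, , ], x[3, , ])
  for (rep in 1:10) {
    C <- sample(c(2, 4, 6, 8), 1); G <- sample(c(1, 2), 1)
    x <- array(rnorm(C * 9), c(C, 3, 3))
    groups <- split_groups(x, G)
    rebuilt <- array(0, dim(x))
    at <- 1
    for (g in groups) {
      rebuilt[at:(at + dim(g)[1] - 1), , ] <- g
      at <- at + dim(g)[1]
    }
    expect_equal(rebuilt, x)
  }
  expect_error(split_groups(x, 3), "divisible")
})

test_that("global descriptor is the exact spatial mean", {
  x <- array(5, c(3, 2, 2))
  expect_equal(global_descriptor(x), rep(5, 3))
  y <- array(0, c(1, 2, 2))
  y[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(global_descriptor(y), 2.5)
  set.seed(10)
  for (rep in 1:20) {
    d <- c(sample(1:4, 1), sample(2:4, 1), sample(2:4, 1))
    x <- array(rnorm(prod(d)), d)
    expect_equal(global_descriptor(x), oracle_descriptor(x), tolerance = 1e-12)
    a <- rnorm(1)
    expect_equal(global_descriptor(a * x), a * global_descriptor(x),
                 tolerance = 1e-12)
  }
})

test_that("fusion preserves shape, attenuates, and treats groups independently", {
  set.seed(11)
  C <- 8; H <- 4; W <- 4
  pars <- fusion_params(C / 2)
  x <- array(rnorm(C * H * W), c(C, H, W))
  y <- fuse(x, pars, G = 2)
  expect_equal(dim(y), dim(x))
  # final sigmoid gate bounds the output by the input magnitude
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  # determinism
  expect_identical(y, fuse(x, pars, G = 2))
  # with shared per-group parameters, G = 2 equals running the block on each
  # channel half independently
  halves <- split_groups(x, 2)
  y1 <- fuse(halves[[1]], pars, G = 1)
  y2 <- fuse(halves[[2]], pars, G = 1)
  expect_equal(y[1:4, , ], y1, tolerance = 1e-12)
  expect_equal(y[5:8, , ], y2, tolerance = 1e-12)
  expect_error(fuse(array(rnorm(8), c(2, 2, 2)), fusion_params(2), G = 1),
               "kernel")
  expect_error(fuse(x, pars, G = 3), "divisible")
})

test_that("cross-attention rows are softmax-normalized aggregations (loop oracle)", {
  set.seed(12)
  mk <- function(D, dk) list(wdq = rmat(D, dk), wdk = rmat(D, dk),
                             wpq = rmat(D, dk), wpk = rmat(D, dk),
                             wdv = rmat(D, D), wpv = rmat(D, D))
  for (rep in 1:20) {
    D <- 4
    fd <- rmat(3, D); fp <- rmat(5, D)
    pars <- mk(D, 4)
    out <- cross_attend(fd, fp, pars)
    o <- oracle_cross_attn(fd, fp, pars)
    expect_equal(out$attn_d, o$attn, tolerance = 1e-6)
    expect_equal(out$z_d, o$z, tolerance = 1e-6)
    expect_equal(rowSums(out$attn_d), rep(1, 3), tolerance = 1e-6)
    expect_equal(rowSums(out$attn_p), rep(1, 5), tolerance = 1e-6)
  }
  # singleton softmax is 1 regardless of logits
  out1 <- cross_attend(rmat(1, 4) * 10, rmat(1, 4) * 10, mk(4, 4))
  expect_equal(as.numeric(out1$attn_d), 1)
  # identical keys give uniform attention over valid positions
  fp_same <- matrix(rep(rnorm(4), each = 6), 6, 4)
  outu <- cross_attend(rmat(2, 4), fp_same, mk(4, 4))
  expect_equal(outu$attn_d, matrix(1 / 6, 2, 6), tolerance = 1e-12)
  # masked keys receive zero weight; all-masked errors
  outm <- cross_attend(rmat(2, 4), rmat(6, 4), mk(4, 4),
                       mask_p = c(1, 1, 1, 0, 0, 0))
  expect_true(all(outm$attn_d[, 4:6] == 0))
  expect_equal(rowSums(outm$attn_d), c(1, 1), tolerance = 1e-12)
  expect_error(cross_attend(rmat(2, 4), rmat(3, 4), mk(4, 4),
                            mask_p = c(0, 0, 0)), "masked")
})

test_that("residual mix is the exact equal-weight average", {
  set.seed(13)
  f <- rmat(4, 6)
  expect_equal(residual_mix(f, f), f)
  expect_equal(residual_mix(matrix(0, 4, 6), f), 0.5 * f)
  for (rep in 1:20) {
    z <- rmat(4, 6)
    expect_equal(residual_mix(z, f), (z + f) / 2, tolerance = 1e-12)
  }
  expect_error(residual_mix(rmat(2, 2), rmat(3, 2)), "equal shapes")
})

test_that("max-pool + concat respects masks and matches the column-max oracle", {
  set.seed(14)
  d1 <- rmat(1, 4); p1 <- rmat(1, 4)
  expect_equal(pool_and_concat(d1, p1), c(d1[1, ], p1[1, ]))
  for (rep in 1:20) {
    df <- rmat(5, 4); pf <- rmat(7, 4)
    f <- pool_and_concat(df, pf)
    expect_equal(f, c(oracle_colmax(df), oracle_colmax(pf)), tolerance = 1e-12)
  }
  # appending masked padding rows leaves the result unchanged
  df <- rmat(5, 4); pf <- rmat(7, 4)
  base <- pool_and_concat(df, pf)
  df2 <- rbind(df, rmat(2, 4) + 100)
  ext <- pool_and_concat(df2, pf, mask_d = c(rep(1, 5), 0, 0))
  expect_equal(ext, base)
  expect_error(pool_and_concat(df, pf, mask_d = rep(0, 5)), "valid rows")
})

test_that("prediction head is a sigmoid-terminated MLP", {
  # zero weights give exactly 0.5
  head0 <- list(list(w = matrix(0, 4, 1), b = 0))
  expect_equal(predict_head(rnorm(4), head0), 0.5)
  # probability increases monotonically in the bias
  set.seed(15)
  w <- rmat(4, 1)
  f <- rnorm(4)
  ps <- vapply(c(-5, -1, 0, 1, 5),
               function(b) predict_head(f, list(list(w = w, b = b))), 0)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
  # single linear layer equals the closed form
  for (rep in 1:20) {
    w <- rmat(6, 1); b <- rnorm(1); f <- rnorm(6)
    expect_equal(predict_head(f, list(list(w = w, b = b))),
                 1 / (1 + exp(-(sum(w * f) + b))), tolerance = 1e-12)
  }
  expect_error(predict_head(rnorm(3), head0), "dimension")
})

test_that("binary cross-entropy matches its closed forms and the loop oracle", {
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(c(0, 1, 1, 0), rep(0.5, 4)), log(2), tolerance = 1e-12)
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    expect_equal(bce_loss(y, p), oracle_bce(y, p), tolerance = 1e-12)
  }
  expect_error(bce_loss(c(0, 2), c(0.5, 0.5)), "labels")
})
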