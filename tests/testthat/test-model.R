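# End-to-end structural properties of the assembled network: wiring of the
# ablation variants, padding invariance, permutation equivariance of the
# graph stage, and consistency between the tape implementation and the
# numeric equation-level operations.

test_that("the drug encoder applies exactly three graph-convolution layers", {
  cfg <- tiny_config()
  theta <- dtifuse:::init_params(cfg)
  gcn_w <- grep("^gcn[0-9]+_w$", names(theta), value = TRUE)
  expect_equal(sort(gcn_w), c("gcn1_w", "gcn2_w", "gcn3_w"))
  # widths chain 74 -> D -> D -> D
  expect_equal(nrow(theta$gcn1_w), 74L)
  expect_equal(ncol(theta$gcn1_w), cfg$d_model)
  expect_equal(dim(theta$gcn2_w), c(cfg$d_model, cfg$d_model))
  expect_equal(dim(theta$gcn3_w), c(cfg$d_model, cfg$d_model))
})

test_that("with fusion ablated the drug branch equals the numeric GCN stack", {
  ns <- asNamespace("dtifuse")
  cfg <- tiny_config(ablation = "single", normalize_adjacency = FALSE)
  m <- untrained_model(cfg)
  smi <- "CC(N)CO"
  fd <- encode_drug(m, smi)
  g <- featurize_atoms(smi, n_d = cfg$n_d)
  # numeric path: three gcn_layer calls on the raw self-loop adjacency
  gd <- ns$grid_dims(cfg$n_d, cfg$grid_w_drug)
  P <- gd["h"] * gd["w"]
  adj <- matrix(0, P, P); adj[1:cfg$n_d, 1:cfg$n_d] <- g$adjacency
  md <- matrix(0, P, 74); md[1:cfg$n_d, ] <- g$node_features
  mask <- c(rep(1, g$n_atoms), rep(0, P - g$n_atoms))
  h <- gcn_layer(md, adj, m$theta$gcn1_w, as.vector(m$theta$gcn1_b), mask = mask)
  h <- gcn_layer(h, adj, m$theta$gcn2_w, as.vector(m$theta$gcn2_b), mask = mask)
  h <- gcn_layer(h, adj, m$theta$gcn3_w, as.vector(m$theta$gcn3_b), mask = mask)
  expect_equal(unname(fd[1:g$n_atoms, ]), unname(h[1:g$n_atoms, ]),
               tolerance = 1e-10)
})

test_that("the tape coordinate-attention block matches the numeric operations", {
  ns <- asNamespace("dtifuse")
  cfg <- tiny_config()
  m <- untrained_model(cfg)
  th <- m$theta
  set.seed(31)
  st <- ns$grid_structures(4L, 4L, 16L, cfg$groups_protein)
  x <- rmat(16, cfg$d_model)
  tp <- ns$ad_tape()
  y_tape <- ns$ad_value(ns$tape_coord_attention(tp, x, th, st))
  # numeric path in the (C, H, W) convention
  xa <- aperm(array(x, c(4, 4, cfg$d_model)), c(3, 2, 1))  # W,H -> C,H,W
  pars <- list(w1 = t(th$ca_w1), b1 = as.vector(th$ca_b1),
               wh = t(th$ca_wh), bh = as.vector(th$ca_bh),
               ww = t(th$ca_ww), bw = as.vector(th$ca_bw))
  ya <- coordinate_attention(xa, coordinate_gates(xa, pars))
  y_num <- matrix(aperm(ya, c(3, 2, 1)), 16, cfg$d_model)
  expect_equal(y_tape, y_num, tolerance = 1e-10)
})

test_that("predictions are invariant to extra padding rows end to end", {
  ns <- asNamespace("dtifuse")
  base <- tiny_config()
  # same grid widths, taller grids: all added cells are masked padding
  wide <- tiny_config(n_d = 24L, theta_p = 24L, grid_w_drug = 4L,
                      grid_w_protein = 4L)
  base$grid_w_drug <- 4L
  base$grid_w_protein <- 4L
  m <- untrained_model(base)           # parameter shapes are grid-free
  recs <- tiny_records(4)
  p_base <- predict(m, recs)
  m2 <- m; m2$config <- wide
  p_wide <- predict(m2, recs)
  expect_equal(p_base, p_wide, tolerance = 1e-12)
})

test_that("the graph stage is atom-permutation equivariant", {
  ns <- asNamespace("dtifuse")
  cfg <- tiny_config(ablation = "single")
  m <- untrained_model(cfg)
  set.seed(33)
  g <- featurize_atoms("NC(CO)CC", n_d = cfg$n_d)
  n <- g$n_atoms
  perm <- sample(n)
  gp <- g
  gp$node_features[1:n, ] <- g$node_features[perm, ]
  gp$adjacency[1:n, 1:n] <- g$adjacency[perm, perm]
  enc <- function(graph) {
    tokens <- dtifuse::tokenize_sequence("ACD", cfg$theta_p)
    prep <- ns$prepare_sample(graph, tokens, cfg)
    tp <- ns$ad_tape(0L, grad = FALSE)
    ns$ad_value(ns$tape_drug_branch(tp, m$theta, prep, cfg))
  }
  out <- enc(g)
  out_p <- enc(gp)
  expect_equal(out_p[1:n, ], out[perm, ], tolerance = 1e-10)
})

test_that("ablation variants rewire the architecture, never the data path", {
  cfg <- tiny_config()
  full <- untrained_model(cfg)
  noco <- untrained_model(tiny_config(ablation = "Noco"))
  single <- untrained_model(tiny_config(ablation = "single"))
  nocross <- untrained_model(tiny_config(ablation = "NoCross"))
  # single: no fusion parameters exist in the checkpoint
  expect_false(any(grepl("fuse", names(single$theta))))
  expect_true(any(grepl("fuse", names(full$theta))))
  # Noco: coordinate attention replaced by a linear layer
  expect_true(all(c("noco_w", "noco_b") %in% names(noco$theta)))
  expect_false(any(grepl("^ca_", names(noco$theta))))
  # NoCross: strictly fewer parameters, no attention projections
  expect_false(any(grepl("^x_", names(nocross$theta))))
  expect_lt(n_parameters(nocross), n_parameters(full))
  # NoCross never computes cross-attention (no z_p in the forward capture)
  ns <- asNamespace("dtifuse")
  recs <- tiny_records(2)
  preps <- ns$prepare_records(recs, nocross$config)
  p <- ns$predict_prepared(nocross$theta, preps, nocross$config, capture = TRUE)
  expect_null(attr(p, "captured")[[1]]$z_p)
  pfull <- ns$predict_prepared(full$theta, ns$prepare_records(recs, cfg), cfg,
                               capture = TRUE)
  expect_false(is.null(attr(pfull, "captured")[[1]]$z_p))
  expect_error(run_ablation("bogus", recs, cfg), "unknown ablation")
})

test_that("probabilities are strictly inside (0,1)", {
  m <- untrained_model()
  recs <- tiny_records(6)
  p <- predict(m, recs)
  expect_true(all(p > 0 & p < 1))
  expect_length(p, 6)
  # scalar interface agrees with the data-frame interface
  p1 <- predict(m, smiles = recs$smiles[1], sequence = recs$sequence[1])
  expect_equal(p1, p[1])
})

test_that("attention rows over valid keys sum to one inside the model", {
  ns <- asNamespace("dtifuse")
  cfg <- tiny_config()
  m <- untrained_model(cfg)
  recs <- tiny_records(4)
  preps <- ns$prepare_records(recs, cfg)
  for (prep in preps) {
    tp <- ns$ad_tape()
    # recompute the attention matrices from the branch outputs
    f_d <- ns$ad_value(ns$tape_drug_branch(tp, m$theta, prep, cfg))
    f_p <- ns$ad_value(ns$tape_protein_branch(tp, m$theta, prep, cfg))
    pars <- list(wdq = m$theta$x_wdq, wdk = m$theta$x_wdk, wdv = m$theta$x_wdv,
                 wpq = m$theta$x_wpq, wpk = m$theta$x_wpk, wpv = m$theta$x_wpv)
    out <- cross_attend(f_d, f_p, pars, mask_d = prep$std$mask,
                        mask_p = prep$stp$mask)
    expect_equal(rowSums(out$attn_d), rep(1, nrow(f_d)), tolerance = 1e-6)
    expect_equal(rowSums(out$attn_p), rep(1, nrow(f_p)), tolerance = 1e-6)
  }
})

test_that("gated-convolution encoder is shape-preserving and off by default", {
  ns <- asNamespace("dtifuse")
  expect_false(tiny_config()$gated_conv)
  cfg <- tiny_config(gated_conv = TRUE)
  m <- untrained_model(cfg)
  expect_true(any(grepl("^gc1_", names(m$theta))))
  fp <- encode_protein(m, "ACDEFGHIKLMNP")
  expect_equal(dim(fp), c(cfg$theta_p, cfg$d_model))
})
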