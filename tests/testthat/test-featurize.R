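test_that("single-atom molecule featurizes to the identity graph", {
  g <- featurize_atoms("C", n_d = 4)
  expect_equal(g$n_atoms, 1)
  expect_equal(dim(g$node_features), c(4L, 74L))
  expect_equal(g$adjacency[1, 1], 1)          # self-loop
  expect_equal(sum(g$adjacency), 1)           # nothing else
  expect_equal(g$node_mask, c(1, 0, 0, 0))
  # methane: C atom type bit, degree 0, 4 implicit H, sp3
  blocks <- atom_feature_blocks()
  f <- g$node_features[1, ]
  expect_equal(which(f != 0), c(1L, 44L, 59L, 66L, 74L))
})

test_that("every atom feature row is 74-dim with one bit per one-hot block", {
  blocks <- atom_feature_blocks()
  expect_equal(sum(blocks$width), 74L)
  onehot <- blocks[!blocks$block %in% c("formal_charge", "radical_electrons",
                                        "aromatic"), ]
  for (smi in c("CCO", "c1ccccc1", "CC(=O)O", "C[NH3+]", "CC(=O)[O-]",
                "N#Cc1ccccc1", "CS(=O)(=O)C")) {
    g <- featurize_atoms(smi, n_d = 20)
    expect_equal(ncol(g$node_features), 74L)
    for (i in seq_len(g$n_atoms)) {
      for (b in seq_len(nrow(onehot))) {
        bits <- g$node_features[i, onehot$start[b]:onehot$end[b]]
        expect_equal(sum(bits != 0), 1,
                     info = sprintf("%s atom %d block %s", smi, i, onehot$block[b]))
      }
    }
  }
})

test_that("ethanol adjacency matches the hand-built bond list", {
  # CCO: bonds 1-2, 2-3; with self-loops row sums are degree + 1
  g <- featurize_atoms("CCO", n_d = 5)
  expect_equal(g$n_atoms, 3)
  hand <- matrix(0, 5, 5)
  hand[1, 2] <- hand[2, 1] <- 1
  hand[2, 3] <- hand[3, 2] <- 1
  diag(hand)[1:3] <- 1
  expect_equal(g$adjacency, hand)
  expect_equal(rowSums(g$adjacency)[1:3], c(2, 3, 2))
})

test_that("adjacency is symmetric with self-loops only on real atoms", {
  for (smi in c("CC(C)CO", "c1ccc(CC(=O)O)cc1", "NCCN")) {
    g <- featurize_atoms(smi, n_d = 24)
    expect_equal(g$adjacency, t(g$adjacency))
    expect_equal(diag(g$adjacency), g$node_mask)
    zero_rows <- rowSums(abs(g$node_features)) == 0
    expect_equal(as.numeric(!zero_rows), g$node_mask)
  }
})

test_that("atom order permutation permutes features and adjacency identically", {
  a <- featurize_atoms("NCO", n_d = 3)   # atoms N, C, O
  b <- featurize_atoms("OCN", n_d = 3)   # same molecule, reversed order
  perm <- c(3, 2, 1)
  expect_equal(a$node_features, b$node_features[perm, ])
  expect_equal(a$adjacency, b$adjacency[perm, perm])
})

test_that("extra padding never alters the leading rows", {
  small <- featurize_atoms("CC(N)CO", n_d = 8)
  big <- featurize_atoms("CC(N)CO", n_d = 30)
  n <- small$n_atoms
  expect_equal(small$node_features[1:n, ], big$node_features[1:n, ])
  expect_equal(small$adjacency[1:n, 1:n], big$adjacency[1:n, 1:n])
})

test_that("unparsable SMILES and oversize molecules are rejected", {
  expect_error(featurize_atoms("not_a_molecule("), "unparsable|conversion")
  expect_error(featurize_atoms("CCCCCCCCCC", n_d = 4), "exceeding the capacity")
})

test_that("batch featurization matches single calls and honors the cache", {
  smis <- c("CCO", "c1ccccc1", "CCO")
  cache <- new.env()
  gs <- featurize_drugs(smis, n_d = 12, cache = cache)
  expect_equal(gs[[1]], featurize_atoms("CCO", n_d = 12))
  expect_equal(gs[[1]], gs[[3]])
  expect_true(!is.null(cache[["CCO"]]))
  # cache hits return identical graphs
  gs2 <- featurize_drugs("CCO", n_d = 12, cache = cache)
  expect_identical(gs2[[1]], cache[["CCO"]])
})

test_that("feature projection is the padded matrix product", {
  g <- featurize_atoms("CCO", n_d = 6)
  # identity-like projection returns the features unchanged
  ident <- project_features(g, diag(74))
  expect_equal(ident$features, g$node_features)
  set.seed(1)
  w <- rmat(8, 74)
  pr <- project_features(g, w)
  # brute-force product oracle
  expected <- matrix(0, 6, 8)
  for (i in 1:6) for (k in 1:8) {
    expected[i, k] <- sum(g$node_features[i, ] * w[k, ])
  }
  expect_equal(pr$features, expected, tolerance = 1e-12)
  expect_true(all(pr$features[4:6, ] == 0))   # zero rows propagate
  expect_error(project_features(g, rmat(8, 10)), "input columns")
})
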