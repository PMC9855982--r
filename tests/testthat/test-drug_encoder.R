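# GNN drug encoder: hand-computed single steps, brute-force loop oracles,
# shape contracts, permutation equivariance and receptive-field growth.

test_that("GCN step reproduces the hand-computed two-node example", {
  g <- prepare_graph(smiles_to_graph("CC"))
  # scalar states [1, 1], W = 1, identity activation:
  # m_v = h_v / |N(v)| + h_w / sqrt(|N(v)||N(w)|) = 1 + 1 = 2
  out <- message_passing_step("GCN", matrix(c(1, 1), 2L),
                              g, list(W = matrix(1)), activation = "identity")
  expect_equal(out, matrix(c(2, 2), 2L))
})

test_that("DMPNN step with empty neighbor sets returns tau(h0)", {
  g <- prepare_graph(smiles_to_graph("CC"))
  set.seed(2)
  h0 <- matrix(rnorm(2L * 3L), 2L, 3L)
  he <- matrix(rnorm(2L * 3L), 2L, 3L)
  # both directed edges have N(src) \ {dst} empty, so messages vanish
  out <- message_passing_step("DMPNN", he, g,
                              list(h0 = h0, Wm = diag(3L)),
                              activation = "identity")
  expect_equal(out, h0)
  out_relu <- message_passing_step("DMPNN", he, g, list(h0 = h0, Wm = diag(3L)))
  expect_equal(out_relu, pmax(h0, 0))
})

test_that("GIN step with identity MLPs on the star K1,3 sums the leaves", {
  g <- prepare_graph(smiles_to_graph("C(C)(C)C"))  # atom 1 is the center
  h <- matrix(c(0.5, 1, 1, 1), 4L)  # center 0.5, leaves 1
  out <- message_passing_step("GIN", h, g, list(msg = NULL, upd = NULL),
                              activation = "identity")
  expect_equal(out[1L, ], 0.5 + 3)   # m_center = 3
  expect_equal(out[2:4, ], rep(1 + 0.5, 3L))  # each leaf sees the center
})

test_that("message passing equals brute-force neighbor-loop oracles on small graphs", {
  d <- 3L
  for (variant in c("GCN", "GAT", "GIN", "MPNN", "DMPNN")) {
    for (smi in oracle_smiles) {
      set.seed(17L + nchar(smi))
      g <- prepare_graph(smiles_to_graph(smi))
      nr <- if (variant == "DMPNN") nrow(g$directed_bonds) else g$atom_count
      H <- matrix(rnorm(nr * d), nr, d)
      p <- rand_layer_params(variant, d, graph = g)
      got <- message_passing_step(variant, H, g, p)
      want <- switch(variant,
        GCN = oracle_gcn_step(H, g, p$W, p$b),
        GAT = oracle_gat_step(H, g, p$heads),
        GIN = oracle_gin_step(H, g, p$msg, p$upd),
        MPNN = oracle_mpnn_step(H, g, p$edge, p$gru),
        DMPNN = oracle_dmpnn_step(H, g, p$h0, p$Wm, p$bm))
      expect_equal(got, want, tolerance = 1e-6,
                   info = paste(variant, smi))
    }
  }
})

test_that("GAT final layer averages heads; hidden layers concatenate", {
  g <- prepare_graph(smiles_to_graph("CCO"))
  set.seed(3)
  d <- 4L
  H <- matrix(rnorm(3L * d), 3L, d)
  p <- rand_layer_params("GAT", d, heads = 2L)
  hidden <- message_passing_step("GAT", H, g, p)
  expect_equal(dim(hidden), c(3L, 2L * d))
  final <- message_passing_step("GAT", H, g, p, final_layer = TRUE)
  expect_equal(dim(final), c(3L, d))
  expect_equal(final, oracle_gat_step(H, g, p$heads, final_layer = TRUE),
               tolerance = 1e-6)
})

test_that("encode_drug returns a finite Na x d matrix for every variant", {
  benz <- smiles_to_graph("c1ccccc1")
  for (variant in c("GCN", "GAT", "GIN", "MPNN", "DMPNN")) {
    cfg <- tiny_config(variant)
    D <- encode_drug(benz, config = cfg)
    expect_s3_class(D, "drug_embedding")
    expect_equal(dim(D$values), c(6L, cfg$embedding_size))
    expect_true(all(is.finite(D$values)), info = variant)
  }
  # edge-dependent variants on a bond-free graph: empty sums, not errors
  single <- smiles_to_graph("C")
  for (variant in c("MPNN", "DMPNN")) {
    D <- encode_drug(single, config = tiny_config(variant))
    expect_equal(dim(D$values), c(1L, 8L))
    expect_true(all(is.finite(D$values)))
  }
})

test_that("unknown variant names raise a configuration error", {
  g <- smiles_to_graph("CC")
  expect_error(message_passing_step("SAGE", matrix(0, 2L, 1L), g, list()),
               "unknown GNN variant")
  expect_error(dta_config(variant = "SAGE"))
})

test_that("atom relabeling permutes embedding rows identically for every variant", {
  # OCC is CCO with atom order reversed
  g1 <- smiles_to_graph("CCO")
  g2 <- smiles_to_graph("OCC")
  perm <- c(3L, 2L, 1L)
  expect_equal(g2$atom_features, g1$atom_features[perm, ])
  for (variant in c("GCN", "GAT", "GIN", "MPNN", "DMPNN")) {
    cfg <- tiny_config(variant)
    params <- dtattn:::init_dta_params(cfg, vocab_size = 20L)
    D1 <- encode_drug(g1, params = params, config = cfg)$values
    D2 <- encode_drug(g2, params = params, config = cfg)$values
    expect_equal(D2, D1[perm, ], tolerance = 1e-10, info = variant)
  }
})

test_that("the receptive field grows by one bond per layer on a path graph", {
  g <- smiles_to_graph("CCCCC")  # P5: distance from atom 1 to atom 5 is 4
  base <- g
  pert <- g
  # swap the element one-hot of the endpoint atom (C -> N)
  pert$atom_features[1L, 1:2] <- c(0, 1)
  for (variant in c("GCN", "GAT", "GIN", "MPNN", "DMPNN")) {
    # DMPNN's node readout pools incoming directed-edge states, which span
    # one extra bond relative to node-state variants.
    reach <- if (variant == "DMPNN") 3L else 4L
    cfg_short <- tiny_config(variant, gnn_layers = reach - 1L)
    params <- dtattn:::init_dta_params(
      tiny_config(variant, gnn_layers = 5L), vocab_size = 20L)
    # keep ReLU units away from their dead zone so the perturbation cannot
    # be silently gated out (zero-bias initialization artifact)
    params <- lapply(params, function(p) if (nrow(p) == 1L) p + 0.1 else p)
    far_unchanged <- encode_drug(base, params = params, config = cfg_short)$values[5L, ]
    far_perturbed <- encode_drug(pert, params = params, config = cfg_short)$values[5L, ]
    expect_equal(far_unchanged, far_perturbed, tolerance = 1e-12,
                 info = paste(variant, "below reach"))
    cfg_reach <- tiny_config(variant, gnn_layers = reach)
    a <- encode_drug(base, params = params, config = cfg_reach)$values[5L, ]
    b <- encode_drug(pert, params = params, config = cfg_reach)$values[5L, ]
    expect_gt(max(abs(a - b)), 1e-8)
  }
})
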