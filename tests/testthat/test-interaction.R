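# Interaction module: relation matrix, significance softmaxes, attended
# features, regression/ablation heads, and end-to-end invariances.

test_that("relation matrix is the row-by-row dot product", {
  D <- diag(2)
  S <- matrix(c(1, 0, 0, 2), 2L, byrow = TRUE)
  expect_equal(relation_matrix(D, S), matrix(c(1, 0, 0, 2), 2L, byrow = TRUE))
  set.seed(8)
  D <- matrix(rnorm(12), 3L, 4L); S <- matrix(rnorm(20), 5L, 4L)
  expect_equal(dim(relation_matrix(D, S)), c(3L, 5L))
  expect_equal(relation_matrix(matrix(0, 3L, 4L), S), matrix(0, 3L, 5L))
  expect_error(relation_matrix(matrix(0, 3L, 4L), matrix(0, 5L, 3L)),
               "dimension mismatch")
})

test_that("significance matrices are the column/row softmaxes of R", {
  expect_equal(substructure_significance(matrix(c(0, 0), 2L)),
               matrix(c(0.5, 0.5), 2L))
  expect_equal(substructure_significance(matrix(c(log(2), 0), 2L)),
               matrix(c(2 / 3, 1 / 3), 2L))
  expect_equal(subsequence_significance(matrix(0, 1L, 3L)),
               matrix(1 / 3, 1L, 3L))
  expect_equal(subsequence_significance(matrix(c(log(3), 0), 1L)),
               matrix(c(3 / 4, 1 / 4), 1L))
  set.seed(11)
  R <- matrix(runif(30, -50, 50), 5L, 6L)
  a <- substructure_significance(R)
  s <- subsequence_significance(R)
  expect_equal(colSums(a), rep(1, 6L), tolerance = 1e-5)
  expect_equal(rowSums(s), rep(1, 5L), tolerance = 1e-5)
  expect_true(all(a >= 0 & a <= 1) && all(s >= 0 & s <= 1))
})

test_that("softmax significances are invariant to constant column shifts", {
  set.seed(12)
  R <- matrix(rnorm(20), 4L, 5L)
  R2 <- R; R2[, 3L] <- R2[, 3L] + 17.5
  a1 <- substructure_significance(R)
  a2 <- substructure_significance(R2)
  expect_equal(a1[, 3L], a2[, 3L], tolerance = 1e-12)
})

test_that("attended drug feature matches degeneracies, closed forms and the loop oracle", {
  set.seed(13)
  # single atom: every column of a is [1]
  D1 <- matrix(rnorm(4), 1L, 4L)
  a1 <- matrix(1, 1L, 5L)
  r <- attended_drug_feature(a1, D1)
  expect_equal(r$D_doubleprime, matrix(rep(D1, each = 5L), 5L))
  expect_equal(r$drug_feature, 5 * D1)
  # uniform significance: drug_feature = Ns * columnwise mean of D
  D <- matrix(rnorm(12), 3L, 4L)
  au <- matrix(1 / 3, 3L, 6L)
  r <- attended_drug_feature(au, D)
  expect_equal(r$drug_feature, matrix(6 * colMeans(D), 1L))
  # random instance vs index-by-index loop
  a <- substructure_significance(matrix(rnorm(12), 3L, 4L))
  D <- matrix(rnorm(6), 3L, 2L)
  want <- oracle_attended_drug(a, D)
  got <- attended_drug_feature(a, D)
  expect_equal(got$D_doubleprime, want$D_doubleprime, tolerance = 1e-6)
  expect_equal(got$drug_feature, want$drug_feature, tolerance = 1e-6)
  expect_error(attended_drug_feature(matrix(1, 2L, 3L), D), "atom rows")
})

test_that("attended protein feature matches degeneracies, closed forms and the loop oracle", {
  set.seed(14)
  # single sub-sequence: s has one column of ones
  S1 <- matrix(rnorm(4), 1L, 4L)
  s1 <- matrix(1, 3L, 1L)
  r <- attended_protein_feature(s1, S1)
  expect_equal(r$protein_feature, 3 * S1)
  # uniform significance: protein_feature = Na * columnwise mean of S
  S <- matrix(rnorm(20), 5L, 4L)
  su <- matrix(1 / 5, 3L, 5L)
  r <- attended_protein_feature(su, S)
  expect_equal(r$protein_feature, matrix(3 * colMeans(S), 1L))
  # random instance vs loop oracle
  s <- subsequence_significance(matrix(rnorm(15), 3L, 5L))
  want <- oracle_attended_protein(s, S)
  got <- attended_protein_feature(s, S)
  expect_equal(got$P_doubleprime, want$P_doubleprime, tolerance = 1e-6)
  expect_equal(got$protein_feature, want$protein_feature, tolerance = 1e-6)
})

test_that("the regression head is deterministic, zero-propagating and protein-sensitive", {
  cfg <- tiny_config()
  params <- dtattn:::init_dta_params(cfg, vocab_size = 20L)
  d <- cfg$embedding_size
  # zero features and a zero final layer produce exactly zero
  pz <- params
  pz[["head.fc3.W"]] <- pz[["head.fc3.W"]] * 0
  expect_equal(predict_affinity(numeric(d), numeric(d), pz), 0)
  # bit-stable at fixed inputs
  set.seed(15)
  df <- rnorm(d); pf <- rnorm(d)
  expect_identical(predict_affinity(df, pf, params),
                   predict_affinity(df, pf, params))
  # output responds to the protein feature with the drug feature fixed
  expect_gt(abs(predict_affinity(df, pf + 0.5, params) -
                predict_affinity(df, pf, params)), 1e-8)
})

test_that("ablation head equals a loop-based max-pool oracle", {
  cfg <- tiny_config()
  params <- dtattn:::init_dta_params(cfg, vocab_size = 20L)
  d <- cfg$embedding_size
  set.seed(16)
  D <- matrix(rnorm(5L * d), 5L); S <- matrix(rnorm(7L * d), 7L)
  pool <- function(M) {
    out <- numeric(ncol(M))
    for (j in seq_len(ncol(M))) {
      best <- M[1L, j]
      for (i in seq_len(nrow(M))) if (M[i, j] > best) best <- M[i, j]
      out[j] <- best
    }
    out
  }
  want <- predict_affinity(pool(D), pool(S), params)
  expect_equal(ablation_concat_head(D, S, params), want, tolerance = 1e-12)
  # a row that dominates element-wise is the pooled drug vector
  Ddom <- rbind(matrix(0, 3L, d), 5 + abs(rnorm(d)))
  expect_equal(ablation_concat_head(Ddom, S, params),
               predict_affinity(Ddom[4L, ], pool(S), params))
  # single-atom degeneracy
  expect_equal(ablation_concat_head(D[1L, , drop = FALSE], S, params),
               predict_affinity(D[1L, ], pool(S), params))
})

test_that("model-level significance matrices are properly normalized", {
  cfg <- tiny_config("GIN")
  m <- dta_model(cfg, tiny_vocab())
  it <- interaction_tensors(m, "CC(=O)Nc1ccccc1", "MAAACDEFGHIKLMNPQRSTVWY")
  expect_equal(colSums(it$a), rep(1, ncol(it$a)), tolerance = 1e-5)
  expect_equal(rowSums(it$s), rep(1, nrow(it$s)), tolerance = 1e-5)
  # acetanilide has 10 heavy atoms; Ns = max_len - 3 (k - 1)
  expect_equal(dim(it$R), c(10L, cfg$max_len - 3L * (cfg$kernel_size - 1L)))
})

test_that("predicted affinity is invariant to atom relabeling for every variant", {
  seqs <- "MKVACDEFGHIKLMNPQRSTVWYA"
  for (variant in c("GCN", "GAT", "GIN", "MPNN", "DMPNN")) {
    m <- dta_model(tiny_config(variant), tiny_vocab())
    p1 <- predict(m, data.frame(smiles = "CCO", sequence = seqs))
    p2 <- predict(m, data.frame(smiles = "OCC", sequence = seqs))
    expect_equal(p1, p2, tolerance = 1e-5, info = variant)
    # relation matrix structure is row-permuted, features unchanged
    t1 <- interaction_tensors(m, "CCO", seqs)
    t2 <- interaction_tensors(m, "OCC", seqs)
    expect_equal(t2$R, t1$R[c(3L, 2L, 1L), ], tolerance = 1e-8)
    expect_equal(t2$drug_feature, t1$drug_feature, tolerance = 1e-8)
    expect_equal(t2$protein_feature, t1$protein_feature, tolerance = 1e-8)
  }
})
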