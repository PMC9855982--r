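# The internal reverse-mode engine: every model gradient path is checked
# against central finite differences, with parameters perturbed off their
# ReLU kinks (zero-bias initialization would otherwise sit exactly at the
# nondifferentiable point).

test_that("end-to-end gradients match finite differences for every variant", {
  d <- data.frame(smiles = "CC(=O)Nc1ccccc1",
                  sequence = "ACDEFGHIKLMNPQRSTVWYAC", affinity = 6.5)
  for (variant in c("GCN", "GAT", "GIN", "MPNN", "DMPNN")) {
    cfg <- dta_config(variant = variant, gnn_layers = 2L,
                      embedding_size = 4L, prot_embed_dim = 4L,
                      conv_channels = c(3L, 5L), fc_sizes = c(7L, 5L),
                      max_len = 25L, kernel_size = 3L, gat_heads = 2L,
                      mpnn_edge_hidden = 4L, dropout = 0, seed = 11L)
    m <- dta_model(cfg, tiny_vocab())
    set.seed(101)
    m$params <- lapply(m$params, function(p) {
      p + matrix(rnorm(length(p), 0, 0.05), nrow(p))
    })
    sm <- dta_prepare(m, d)[[1L]]
    tape <- dtattn:::ad_tape()
    pn <- dtattn:::params_to_nodes(tape, m$params)
    out <- dtattn:::model_forward(tape, pn, cfg, sm)
    loss <- dtattn:::ad_mse_loss(tape, list(out$pred), 6.5)
    dtattn:::ad_backward(tape, loss)
    f <- function(params) {
      t2 <- dtattn:::ad_tape()
      pn2 <- dtattn:::params_to_nodes(t2, params)
      (dtattn:::model_forward(t2, pn2, cfg, sm)$pred$value[1L, 1L] - 6.5)^2
    }
    for (nm in names(m$params)) {
      p <- m$params
      i <- sample(length(p[[nm]]), 1L)
      eps <- 1e-5
      p[[nm]][i] <- p[[nm]][i] + eps; up <- f(p)
      p[[nm]][i] <- p[[nm]][i] - 2 * eps; dn <- f(p)
      num <- (up - dn) / (2 * eps)
      ana <- pn[[nm]]$grad
      ana <- if (is.null(ana)) 0 else ana[i]
      if (abs(num) > 1e-8 || abs(ana) > 1e-8) {
        expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-3,
                  label = paste(variant, nm, "gradient relative error"))
      }
    }
  }
})

test_that("the ablation head gradient path is also correct", {
  d <- data.frame(smiles = "CCO", sequence = "ACDEFGHIKLMNPQRSTVWY",
                  affinity = 5.5)
  cfg <- dta_config(variant = "GCN", gnn_layers = 2L, embedding_size = 4L,
                    prot_embed_dim = 4L, conv_channels = c(3L, 5L),
                    fc_sizes = c(7L, 5L), max_len = 25L, kernel_size = 3L,
                    dropout = 0, seed = 13L)
  m <- dta_model(cfg, tiny_vocab())
  set.seed(103)
  m$params <- lapply(m$params, function(p) {
    p + matrix(rnorm(length(p), 0, 0.05), nrow(p))
  })
  sm <- dta_prepare(m, d)[[1L]]
  tape <- dtattn:::ad_tape()
  pn <- dtattn:::params_to_nodes(tape, m$params)
  out <- dtattn:::model_forward(tape, pn, cfg, sm, ablation = TRUE)
  loss <- dtattn:::ad_mse_loss(tape, list(out$pred), 5.5)
  dtattn:::ad_backward(tape, loss)
  f <- function(params) {
    t2 <- dtattn:::ad_tape()
    pn2 <- dtattn:::params_to_nodes(t2, params)
    (dtattn:::model_forward(t2, pn2, cfg, sm,
                            ablation = TRUE)$pred$value[1L, 1L] - 5.5)^2
  }
  # the loss must be sensitive to the head (max pooling routes gradient
  # through the argmax rows only, so some entries legitimately have zero
  # gradient)
  expect_gt(max(abs(pn[["head.fc1.W"]]$grad)), 0)
  for (nm in c("head.fc1.W", "head.fc2.W", "drug.proj.W", "prot.conv2.W")) {
    p <- m$params
    i <- sample(length(p[[nm]]), 1L)
    eps <- 1e-5
    p[[nm]][i] <- p[[nm]][i] + eps; up <- f(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * eps; dn <- f(p)
    num <- (up - dn) / (2 * eps)
    ana <- pn[[nm]]$grad
    ana <- if (is.null(ana)) 0 else ana[i]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-3,
              label = nm)
  }
})

test_that("valid 1D convolution via im2col matches a direct sliding-window oracle", {
  set.seed(104)
  L <- 12L; Cin <- 3L; Cout <- 2L; k <- 4L
  X <- matrix(rnorm(L * Cin), L, Cin)
  W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
  b <- matrix(rnorm(Cout), 1L)
  tape <- dtattn:::ad_tape()
  xn <- dtattn:::ad_leaf(tape, X)
  out <- dtattn:::ad_add_bias(tape,
    dtattn:::ad_matmul(tape, dtattn:::ad_im2col(tape, xn, k),
                       dtattn:::ad_leaf(tape, W)),
    dtattn:::ad_leaf(tape, b))$value
  # direct oracle: window rows stacked offset-major (offset block j = X row i+j-1)
  want <- matrix(0, L - k + 1L, Cout)
  for (i in seq_len(L - k + 1L)) {
    for (o in seq_len(Cout)) {
      acc <- b[1L, o]
      for (j in seq_len(k)) {
        for (c in seq_len(Cin)) {
          acc <- acc + X[i + j - 1L, c] * W[(j - 1L) * Cin + c, o]
        }
      }
      want[i, o] <- acc
    }
  }
  expect_equal(out, want, tolerance = 1e-12)
})
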