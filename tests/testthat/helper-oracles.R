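# Independent brute-force oracles and small fixtures shared across tests.
# Oracles are written as plain double loops over neighbor lists / index
# triples, deliberately independent of the package's vectorized paths.

# neighbor list from a mol_graph
nbrs_of <- function(graph) {
  lapply(seq_len(graph$atom_count), function(v) {
    db <- graph$directed_bonds
    sort(unique(db[db[, 2L] == v, 1L]))
  })
}

relu_num <- function(x) pmax(x, 0)

lrelu_num <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

mlp2_num <- function(x, p, act = relu_num) {
  h <- act(sweep(x %*% p$W1, 2L, as.numeric(p$b1), "+"))
  sweep(h %*% p$W2, 2L, as.numeric(p$b2), "+")
}

# Table-row message passing oracles, one atom at a time.
oracle_gcn_step <- function(H, graph, W, b = NULL, act = relu_num) {
  nb <- nbrs_of(graph)
  m <- matrix(0, nrow(H), ncol(H))
  for (v in seq_len(nrow(H))) {
    dv <- max(length(nb[[v]]), 1)
    m[v, ] <- H[v, ] / dv
    for (w in nb[[v]]) {
      m[v, ] <- m[v, ] + H[w, ] / sqrt(dv * max(length(nb[[w]]), 1))
    }
  }
  out <- m %*% W
  if (!is.null(b)) out <- sweep(out, 2L, as.numeric(b), "+")
  act(out)
}

oracle_gat_step <- function(H, graph, heads, act = relu_num,
                            final_layer = FALSE) {
  nb <- nbrs_of(graph)
  outs <- lapply(heads, function(hp) {
    HW <- H %*% hp$W
    m <- matrix(0, nrow(H), ncol(HW))
    for (v in seq_len(nrow(H))) {
      cand <- sort(unique(c(v, nb[[v]])))
      e <- vapply(cand, function(w) {
        lrelu_num(sum(HW[v, ] * hp$a1) + sum(HW[w, ] * hp$a2))
      }, numeric(1L))
      alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
      for (k in seq_along(cand)) {
        m[v, ] <- m[v, ] + alpha[k] * HW[cand[k], ]
      }
    }
    act(m)
  })
  if (final_layer) {
    Reduce(`+`, outs) / length(outs)
  } else {
    do.call(cbind, outs)
  }
}

oracle_gin_step <- function(H, graph, msg, upd, act = relu_num) {
  nb <- nbrs_of(graph)
  msg_of <- if (is.null(msg)) function(x) x else function(x) mlp2_num(x, msg, act)
  T_ <- msg_of(H)
  m <- matrix(0, nrow(H), ncol(H))
  for (v in seq_len(nrow(H))) {
    for (w in nb[[v]]) m[v, ] <- m[v, ] + T_[w, ]
  }
  s <- H + m
  if (is.null(upd)) s else mlp2_num(s, upd, act)
}

sigmoid_num <- function(x) 1 / (1 + exp(-x))

oracle_gru <- function(h, m, g) {
  r <- sigmoid_num(sweep(m %*% g$Wir, 2, as.numeric(g$bir), "+") +
                   sweep(h %*% g$Whr, 2, as.numeric(g$bhr), "+"))
  z <- sigmoid_num(sweep(m %*% g$Wiz, 2, as.numeric(g$biz), "+") +
                   sweep(h %*% g$Whz, 2, as.numeric(g$bhz), "+"))
  n <- tanh(sweep(m %*% g$Win, 2, as.numeric(g$bin), "+") +
            r * sweep(h %*% g$Whn, 2, as.numeric(g$bhn), "+"))
  (1 - z) * n + z * h
}

oracle_mpnn_step <- function(H, graph, edge, gru, act = relu_num) {
  d <- ncol(H)
  db <- graph$directed_bonds
  m <- matrix(0, nrow(H), d)
  if (nrow(db)) {
    A <- mlp2_num(graph$bond_features, edge, act)
    for (e in seq_len(nrow(db))) {
      Ae <- matrix(A[e, ], d, d)  # column-major, as in the implementation
      m[db[e, 2L], ] <- m[db[e, 2L], ] + as.numeric(Ae %*% H[db[e, 1L], ])
    }
  }
  oracle_gru(H, m, gru)
}

oracle_dmpnn_step <- function(He, graph, h0, Wm, bm = NULL, act = relu_num) {
  db <- graph$directed_bonds
  ne <- nrow(db)
  m <- matrix(0, ne, ncol(He))
  if (ne) {
    key <- paste(db[, 1L], db[, 2L])
    for (i in seq_len(ne)) {
      v <- db[i, 1L]; w <- db[i, 2L]
      for (j in seq_len(ne)) {
        # incoming edge k -> v with k != w
        if (db[j, 2L] == v && db[j, 1L] != w) m[i, ] <- m[i, ] + He[j, ]
      }
    }
  }
  out <- m %*% Wm
  if (!is.null(bm)) out <- sweep(out, 2L, as.numeric(bm), "+")
  act(h0 + out)
}

# O(n^2) pair-count concordance index.
oracle_ci <- function(pred, truth) {
  num <- 0; z <- 0
  n <- length(pred)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (truth[i] > truth[j]) {
        z <- z + 1
        dx <- pred[i] - pred[j]
        num <- num + if (dx > 0) 1 else if (dx == 0) 0.5 else 0
      }
    }
  }
  num / z
}

# Index-by-index attended-feature oracles.
oracle_attended_drug <- function(a, D) {
  Na <- nrow(D); Ns <- ncol(a); d <- ncol(D)
  Dpp <- matrix(0, Ns, d)
  for (j in seq_len(Ns)) {
    for (i in seq_len(Na)) {
      for (bcol in seq_len(d)) {
        Dpp[j, bcol] <- Dpp[j, bcol] + a[i, j] * D[i, bcol]
      }
    }
  }
  feat <- matrix(0, 1L, d)
  for (j in seq_len(Ns)) feat <- feat + Dpp[j, , drop = FALSE]
  list(D_doubleprime = Dpp, drug_feature = feat)
}

oracle_attended_protein <- function(s, S) {
  Na <- nrow(s); Ns <- nrow(S); d <- ncol(S)
  Ppp <- matrix(0, Na, d)
  for (i in seq_len(Na)) {
    for (j in seq_len(Ns)) {
      for (bcol in seq_len(d)) {
        Ppp[i, bcol] <- Ppp[i, bcol] + s[i, j] * S[j, bcol]
      }
    }
  }
  feat <- matrix(0, 1L, d)
  for (i in seq_len(Na)) feat <- feat + Ppp[i, , drop = FALSE]
  list(P_doubleprime = Ppp, protein_feature = feat)
}

# random layer parameters for oracle comparisons
rand_mat <- function(nr, nc) matrix(rnorm(nr * nc, 0, 0.5), nr, nc)

rand_layer_params <- function(variant, d, graph = NULL, edge_hidden = 4L,
                              heads = 2L) {
  switch(variant,
    GCN = list(W = rand_mat(d, d), b = rand_mat(1L, d)),
    GAT = list(heads = lapply(seq_len(heads), function(k) {
      list(W = rand_mat(d, d), a1 = rand_mat(d, 1L), a2 = rand_mat(d, 1L))
    })),
    GIN = list(msg = list(W1 = rand_mat(d, d), b1 = rand_mat(1L, d),
                          W2 = rand_mat(d, d), b2 = rand_mat(1L, d)),
               upd = list(W1 = rand_mat(d, d), b1 = rand_mat(1L, d),
                          W2 = rand_mat(d, d), b2 = rand_mat(1L, d))),
    MPNN = list(edge = list(W1 = rand_mat(14L, edge_hidden),
                            b1 = rand_mat(1L, edge_hidden),
                            W2 = rand_mat(edge_hidden, d * d),
                            b2 = rand_mat(1L, d * d)),
                gru = {
                  g <- list()
                  for (nm in c("Wir", "Whr", "Wiz", "Whz", "Win", "Whn")) {
                    g[[nm]] <- rand_mat(d, d)
                  }
                  for (nm in c("bir", "bhr", "biz", "bhz", "bin", "bhn")) {
                    g[[nm]] <- rand_mat(1L, d)
                  }
                  g
                }),
    DMPNN = list(h0 = rand_mat(nrow(graph$directed_bonds), d),
                 Wm = rand_mat(d, d), bm = rand_mat(1L, d)))
}

# small shared fixtures -------------------------------------------------------

tiny_vocab <- function() build_vocab("ACDEFGHIKLMNPQRSTVWY")

tiny_config <- function(variant = "GCN", gnn_layers = 2L, dropout = 0,
                        seed = 7L, ...) {
  dta_config(variant = variant, gnn_layers = gnn_layers, embedding_size = 8L,
             prot_embed_dim = 8L, conv_channels = c(4L, 6L),
             fc_sizes = c(16L, 8L), max_len = 50L, kernel_size = 4L,
             dropout = dropout, mpnn_edge_hidden = 4L, seed = seed, ...)
}

oracle_smiles <- c("C", "CC", "CCO", "C=CC", "CC(C)O", "C1CC1")
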