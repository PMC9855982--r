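# Drug embedding matrix D (Na x d) from a molecular graph via one of five
# message-passing variants:
#
#   GCN    m_v = sum_{w in N(v) U {v}} h_w / c_wv,  c_wv = sqrt(|N(v)||N(w)|),
#          c_vv = |N(v)|;  h'_v = sigma(m_v W)
#   GAT    alpha_vw = softmax_v(LeakyReLU(a1'Wh_v + a2'Wh_w)) over N(v) U {v};
#          per head m_v = sigma(sum_w alpha_vw W h_w); heads concatenated on
#          hidden layers, averaged on the final layer
#   GIN    m_v = sum_{w in N(v)} MLP(h_w);  h'_v = MLP(h_v + m_v)
#          (literal form: no (1 + eps) self-weight)
#   MPNN   m_v = sum_{w in N(v)} A(e_vw) h_w with edge network A;
#          h'_v = GRU(h_v, m_v)
#   DMPNN  directed-edge states; m_vw = sum_{k in N(v) \ w} h_kv;
#          h'_vw = tau(h0_vw + W_m m_vw)
#
# Empty neighborhoods are empty sums, never errors.

gnn_variants <- c("GCN", "GAT", "GIN", "MPNN", "DMPNN")

# Structural constants reused across layers and epochs; computed once per
# graph and cached on it.
graph_constants <- function(graph) {
  if (!is.null(graph$constants)) return(graph$constants)
  na <- graph$atom_count
  adj <- matrix(0, na, na)
  db <- graph$directed_bonds
  ne <- nrow(db)
  if (ne) adj[db] <- 1
  deg <- rowSums(adj)
  # GCN normalized adjacency with self-loops: off-diagonal 1/sqrt(dv dw),
  # diagonal 1/dv with degree-0 guarded as 1.
  dsafe <- pmax(deg, 1)
  gcn <- adj / sqrt(outer(dsafe, dsafe))
  diag(gcn) <- 1 / dsafe
  gat_mask <- adj + diag(na)
  rev_edge <- integer(ne)
  if (ne) {
    key <- paste(db[, 1L], db[, 2L])
    rev_edge <- match(paste(db[, 2L], db[, 1L]), key)
  }
  # DMPNN aggregation: edge i = (u -> v) receives sum over edges j = (k -> u),
  # k != v, i.e. incoming edges of its source except its own reverse.
  agg <- matrix(0, ne, ne)
  inc <- matrix(0, na, ne)
  if (ne) {
    for (i in seq_len(ne)) {
      js <- which(db[, 2L] == db[i, 1L])
      js <- js[js != rev_edge[i]]
      agg[i, js] <- 1
      inc[db[i, 2L], i] <- 1
    }
  }
  list(adj = adj, deg = deg, gcn = gcn, gat_mask = gat_mask,
       edges = db, rev_edge = rev_edge, dmpnn_agg = agg, dmpnn_inc = inc)
}

#' Attach cached structural constants to a molecular graph
#'
#' Precomputes the adjacency, GCN normalisation, attention mask and
#' directed-edge aggregation operators used by the encoders. Called lazily by
#' the encoders; exposed so datasets can be prepared up front.
#'
#' @param graph A `mol_graph`.
#' @return The graph with a `constants` element attached.
#' @export
prepare_graph <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  graph$constants <- graph_constants(graph)
  graph
}

act_fun <- function(tape, x, activation) {
  switch(activation,
         relu = ad_relu(tape, x),
         identity = x,
         tanh = ad_tanh(tape, x),
         stop("unknown activation: ", activation))
}

# Optional-bias dense used by steps whose printed form has no bias term.
dense_maybe_bias <- function(tape, x, W, b = NULL) {
  out <- ad_matmul(tape, x, W)
  if (!is.null(b)) out <- ad_add_bias(tape, out, b)
  out
}

mlp2 <- function(tape, x, W1, b1, W2, b2, activation) {
  h <- act_fun(tape, dense_maybe_bias(tape, x, W1, b1), activation)
  dense_maybe_bias(tape, h, W2, b2)
}

gru_update <- function(tape, h, m, g) {
  r <- ad_sigmoid(tape, ad_add(tape,
        ad_add_bias(tape, ad_matmul(tape, m, g$Wir), g$bir),
        ad_add_bias(tape, ad_matmul(tape, h, g$Whr), g$bhr)))
  z <- ad_sigmoid(tape, ad_add(tape,
        ad_add_bias(tape, ad_matmul(tape, m, g$Wiz), g$biz),
        ad_add_bias(tape, ad_matmul(tape, h, g$Whz), g$bhz)))
  n <- ad_tanh(tape, ad_add(tape,
        ad_add_bias(tape, ad_matmul(tape, m, g$Win), g$bin),
        ad_mul(tape, r, ad_add_bias(tape, ad_matmul(tape, h, g$Whn), g$bhn))))
  # h' = (1 - z) * n + z * h  (GRU cell convention)
  ad_add(tape, ad_mul(tape, ad_one_minus(tape, z), n), ad_mul(tape, z, h))
}

# One message-passing step on the tape. `states` is the node-state node
# (Na x d), except for DMPNN where it is the directed-edge state node
# (2B x d). `layer` is a named list of parameter nodes for this layer.
gnn_step <- function(tape, variant, states, graph, layer,
                     activation = "relu", final_layer = FALSE) {
  cst <- graph_constants(graph)
  switch(variant,
    GCN = {
      m <- ad_lmul_const(tape, cst$gcn, states)
      act_fun(tape, dense_maybe_bias(tape, m, layer$W, layer$b), activation)
    },
    GAT = {
      heads <- lapply(layer$heads, function(hp) {
        hw <- ad_matmul(tape, states, hp$W)
        s1 <- ad_matmul(tape, hw, hp$a1)
        s2 <- ad_matmul(tape, hw, hp$a2)
        scores <- ad_leaky_relu(tape, ad_outer_sum(tape, s1, s2))
        alpha <- ad_softmax_rows(tape, scores, mask = cst$gat_mask)
        act_fun(tape, ad_matmul(tape, alpha, hw), activation)
      })
      if (final_layer) {
        out <- heads[[1L]]
        if (length(heads) > 1L) {
          for (k in 2L:length(heads)) out <- ad_add(tape, out, heads[[k]])
          out <- ad_mul_const(tape, out, 1 / length(heads))
        }
        out
      } else {
        out <- heads[[1L]]
        if (length(heads) > 1L) {
          for (k in 2L:length(heads)) out <- ad_cbind(tape, out, heads[[k]])
        }
        out
      }
    },
    GIN = {
      msg <- if (is.null(layer$msg)) {
        states
      } else {
        mlp2(tape, states, layer$msg$W1, layer$msg$b1, layer$msg$W2,
             layer$msg$b2, activation)
      }
      m <- ad_lmul_const(tape, cst$adj, msg)
      s <- ad_add(tape, states, m)
      if (is.null(layer$upd)) {
        s
      } else {
        mlp2(tape, s, layer$upd$W1, layer$upd$b1, layer$upd$W2, layer$upd$b2,
             activation)
      }
    },
    MPNN = {
      ef <- ad_leaf(tape, graph$bond_features)
      arows <- mlp2(tape, ef, layer$edge$W1, layer$edge$b1, layer$edge$W2,
                    layer$edge$b2, activation)
      m <- ad_edge_message(tape, arows, states, cst$edges, graph$atom_count)
      gru_update(tape, states, m, layer$gru)
    },
    DMPNN = {
      m <- ad_lmul_const(tape, cst$dmpnn_agg, states)
      upd <- dense_maybe_bias(tape, m, layer$Wm, layer$bm)
      act_fun(tape, ad_add(tape, layer$h0, upd), activation)
    },
    stop("unknown GNN variant: '", variant, "'"))
}

# Collect the parameter nodes of one layer into the structure gnn_step wants.
layer_param_nodes <- function(pnodes, variant, l, gat_heads) {
  pre <- sprintf("drug.l%d.", l)
  switch(variant,
    GCN = list(W = pnodes[[paste0(pre, "W")]], b = pnodes[[paste0(pre, "b")]]),
    GAT = list(heads = lapply(seq_len(gat_heads), function(k) {
      hp <- sprintf("%sh%d.", pre, k)
      list(W = pnodes[[paste0(hp, "W")]], a1 = pnodes[[paste0(hp, "a1")]],
           a2 = pnodes[[paste0(hp, "a2")]])
    })),
    GIN = list(
      msg = list(W1 = pnodes[[paste0(pre, "msg.W1")]],
                 b1 = pnodes[[paste0(pre, "msg.b1")]],
                 W2 = pnodes[[paste0(pre, "msg.W2")]],
                 b2 = pnodes[[paste0(pre, "msg.b2")]]),
      upd = list(W1 = pnodes[[paste0(pre, "upd.W1")]],
                 b1 = pnodes[[paste0(pre, "upd.b1")]],
                 W2 = pnodes[[paste0(pre, "upd.W2")]],
                 b2 = pnodes[[paste0(pre, "upd.b2")]])),
    MPNN = list(
      edge = list(W1 = pnodes[[paste0(pre, "edge.W1")]],
                  b1 = pnodes[[paste0(pre, "edge.b1")]],
                  W2 = pnodes[[paste0(pre, "edge.W2")]],
                  b2 = pnodes[[paste0(pre, "edge.b2")]]),
      gru = list(Wir = pnodes[[paste0(pre, "gru.Wir")]],
                 Whr = pnodes[[paste0(pre, "gru.Whr")]],
                 bir = pnodes[[paste0(pre, "gru.bir")]],
                 bhr = pnodes[[paste0(pre, "gru.bhr")]],
                 Wiz = pnodes[[paste0(pre, "gru.Wiz")]],
                 Whz = pnodes[[paste0(pre, "gru.Whz")]],
                 biz = pnodes[[paste0(pre, "gru.biz")]],
                 bhz = pnodes[[paste0(pre, "gru.bhz")]],
                 Win = pnodes[[paste0(pre, "gru.Win")]],
                 Whn = pnodes[[paste0(pre, "gru.Whn")]],
                 bin = pnodes[[paste0(pre, "gru.bin")]],
                 bhn = pnodes[[paste0(pre, "gru.bhn")]])),
    DMPNN = list(Wm = pnodes[[paste0(pre, "Wm")]],
                 bm = pnodes[[paste0(pre, "bm")]]))
}

# Full drug encoder on the tape: input projection of the 78-dim atom
# features to d, then gnn_layers message-passing steps. Returns the Na x d
# node. For DMPNN the directed-edge states are aggregated back to atoms.
drug_encoder_forward <- function(tape, graph, pnodes, config) {
  x <- ad_leaf(tape, graph$atom_features)
  h <- ad_relu(tape, ad_add_bias(tape,
        ad_matmul(tape, x, pnodes[["drug.proj.W"]]), pnodes[["drug.proj.b"]]))
  variant <- config$variant
  L <- config$gnn_layers
  if (variant == "DMPNN") {
    cst <- graph_constants(graph)
    src <- cst$edges[, 1L]
    hsrc <- if (length(src)) {
      ad_rows(tape, h, src)
    } else {
      ad_leaf(tape, matrix(0, 0L, config$embedding_size))
    }
    ef <- ad_leaf(tape, graph$bond_features)
    h0 <- ad_relu(tape, ad_add_bias(tape,
            ad_matmul(tape, ad_cbind(tape, hsrc, ef), pnodes[["drug.init.W"]]),
            pnodes[["drug.init.b"]]))
    he <- h0
    for (l in seq_len(L)) {
      layer <- layer_param_nodes(pnodes, variant, l, config$gat_heads)
      layer$h0 <- h0
      he <- gnn_step(tape, variant, he, graph, layer)
    }
    nodes_in <- ad_lmul_const(tape, cst$dmpnn_inc, he)
    ad_relu(tape, ad_add_bias(tape,
      ad_matmul(tape, nodes_in, pnodes[["drug.out.W"]]),
      pnodes[["drug.out.b"]]))
  } else {
    for (l in seq_len(L)) {
      layer <- layer_param_nodes(pnodes, variant, l, config$gat_heads)
      h <- gnn_step(tape, variant, h, graph, layer,
                    final_layer = (l == L))
    }
    h
  }
}

#' One message-passing step of a GNN variant
#'
#' Applies a single message-passing + update step to the given node states
#' (or, for DMPNN, directed-edge states) and returns the new states. This is
#' the same computation the full encoder runs per layer, exposed for
#' inspection and testing.
#'
#' @param variant One of `"GCN"`, `"GAT"`, `"GIN"`, `"MPNN"`, `"DMPNN"`.
#' @param node_states Numeric matrix of current states: `Na x d` for node
#'   variants, `2B x d` (one row per directed bond, in `graph$directed_bonds`
#'   order) for DMPNN.
#' @param graph A `mol_graph`.
#' @param params Named list of layer weights (numeric matrices):
#'   * GCN: `W`, optional `b`;
#'   * GAT: `heads`, a list of `list(W, a1, a2)` per head (hidden-layer
#'     concatenation; set `final_layer = TRUE` for head averaging);
#'   * GIN: `msg` and `upd`, each `list(W1, b1, W2, b2)` two-layer MLPs, or
#'     `NULL` for the identity;
#'   * MPNN: `edge` = `list(W1, b1, W2, b2)` edge network mapping 14 bond
#'     features to a column-major `d x d` matrix, and `gru` with fields
#'     `Wir, Whr, bir, bhr, Wiz, Whz, biz, bhz, Win, Whn, bin, bhn`;
#'   * DMPNN: `h0` (initial directed-edge states, `2B x d`), `Wm`, optional
#'     `bm`.
#' @param activation Nonlinearity applied where the variant's update uses
#'   one: `"relu"` (default), `"identity"`, or `"tanh"`.
#' @param final_layer For GAT: average heads instead of concatenating.
#' @return Numeric matrix of updated states.
#' @export
message_passing_step <- function(variant, node_states, graph, params,
                                 activation = "relu", final_layer = FALSE) {
  if (!variant %in% gnn_variants) {
    stop("unknown GNN variant: '", variant, "' (expected one of ",
         paste(gnn_variants, collapse = ", "), ")")
  }
  stopifnot(inherits(graph, "mol_graph"))
  node_states <- as.matrix(node_states)
  expected_rows <- if (variant == "DMPNN") nrow(graph$directed_bonds) else graph$atom_count
  if (nrow(node_states) != expected_rows) {
    stop("node_states has ", nrow(node_states), " rows; expected ",
         expected_rows)
  }
  tape <- ad_tape()
  to_nodes <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) lapply(x, to_nodes) else ad_leaf(tape, x)
  }
  layer <- to_nodes(params)
  st <- ad_leaf(tape, node_states)
  out <- gnn_step(tape, variant, st, graph, layer, activation = activation,
                  final_layer = final_layer)
  out$value
}

#' Encode a drug as a per-atom embedding matrix
#'
#' Runs the input projection and `num_layers` message-passing steps of the
#' chosen variant, returning the drug embedding matrix `D` with one row per
#' atom. Each row summarizes the atom's substructure out to `num_layers`
#' bonds.
#'
#' @param graph A `mol_graph`.
#' @param variant GNN variant (see [message_passing_step()]).
#' @param num_layers Number of message-passing layers.
#' @param params Flat named parameter list as produced by model
#'   construction; if `NULL`, fresh seeded parameters are drawn from
#'   `config`.
#' @param config A `dta_config`; defaults to `dta_config(variant =
#'   variant, gnn_layers = num_layers)`.
#' @return A `drug_embedding` object: list with `values` (`Na x d`),
#'   `variant` and `num_layers`.
#' @export
encode_drug <- function(graph, variant = "GCN", num_layers = 3L,
                        params = NULL, config = NULL) {
  if (is.null(config)) {
    config <- dta_config(variant = variant, gnn_layers = num_layers)
  }
  stopifnot(inherits(graph, "mol_graph"))
  if (is.null(params)) params <- init_dta_params(config, vocab_size = 25L)
  tape <- ad_tape()
  pnodes <- params_to_nodes(tape, params)
  d <- drug_encoder_forward(tape, graph, pnodes, config)
  structure(list(values = d$value, variant = config$variant,
                 num_layers = config$gnn_layers), class = "drug_embedding")
}
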