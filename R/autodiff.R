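# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a node: an environment holding `value`
# (a base matrix), `grad` (accumulated, same shape, NULL until touched),
# `parents` and a `backward` closure that pushes `grad` into the parents.
# Nodes are recorded on a tape in creation order; ad_backward() walks the
# tape in reverse, which is a valid topological order by construction.
#
# The engine is deliberately small: only the operations the affinity model
# needs exist, and all values are plain numeric matrices (scalars are 1x1).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- n
  nd$id <- n
  tape$nodes[[n]] <- nd
  nd
}

# Leaf with gradient accumulation (parameters and inputs).
ad_leaf <- function(tape, value) {
  ad_node(tape, as.matrix(value))
}

ad_is_node <- function(x) is.environment(x) && !is.null(x$value)

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Run backward from scalar node `out`; afterwards leaf$grad holds d out / d leaf.
ad_backward <- function(tape, out) {
  stopifnot(length(out$value) == 1L)
  out$grad <- matrix(1, 1L, 1L)
  for (i in seq(out$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

## ---- operations -----------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad %*% t(nd$parents[[2L]]$value))
    ad_accum(nd$parents[[2L]], crossprod(nd$parents[[1L]]$value, nd$grad))
  })
}

# Multiply by a constant matrix on the left (e.g. a normalized adjacency):
# no gradient flows into the constant.
ad_lmul_const <- function(tape, M, a) {
  force(M)
  ad_node(tape, M %*% a$value, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], crossprod(M, nd$grad))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], nd$grad)
  })
}

# Add a 1 x c bias row vector to every row of an n x c matrix.
ad_add_bias <- function(tape, a, bias) {
  v <- a$value
  ad_node(tape, sweep(v, 2L, as.numeric(bias$value), "+"), list(a, bias),
          function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$value)
    ad_accum(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$value)
  })
}

ad_mul_const <- function(tape, a, M) {
  force(M)
  ad_node(tape, a$value * M, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * M)
  })
}

ad_one_minus <- function(tape, a) {
  ad_node(tape, 1 - a$value, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], -nd$grad)
  })
}

ad_relu <- function(tape, a) {
  v <- a$value
  ad_node(tape, pmax(v, 0), list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * (nd$parents[[1L]]$value > 0))
  })
}

ad_leaky_relu <- function(tape, a, slope = 0.2) {
  v <- a$value
  ad_node(tape, ifelse(v > 0, v, slope * v), list(a), function(nd) {
    x <- nd$parents[[1L]]$value
    ad_accum(nd$parents[[1L]], nd$grad * ifelse(x > 0, 1, slope))
  })
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  force(s)
  ad_node(tape, s, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * s * (1 - s))
  })
}

ad_tanh <- function(tape, a) {
  s <- tanh(a$value)
  force(s)
  ad_node(tape, s, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * (1 - s^2))
  })
}

# Row-wise softmax with max-subtraction stabilisation; `mask` (0/1 constant,
# same shape) restricts the support, e.g. to graph neighborhoods. Fully
# masked rows yield all-zero rows.
ad_softmax_rows <- function(tape, a, mask = NULL) {
  x <- a$value
  if (!is.null(mask)) x[mask == 0] <- -Inf
  mx <- apply(x, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(x - mx)
  if (!is.null(mask)) e[mask == 0] <- 0
  z <- rowSums(e)
  z[z == 0] <- 1
  s <- e / z
  force(s)
  ad_node(tape, s, list(a), function(nd) {
    g <- nd$grad
    ad_accum(nd$parents[[1L]], s * (g - rowSums(g * s)))
  })
}

ad_softmax_cols <- function(tape, a, mask = NULL) {
  x <- a$value
  if (!is.null(mask)) x[mask == 0] <- -Inf
  mx <- apply(x, 2L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(sweep(x, 2L, mx))
  if (!is.null(mask)) e[mask == 0] <- 0
  z <- colSums(e)
  z[z == 0] <- 1
  s <- sweep(e, 2L, z, "/")
  force(s)
  ad_node(tape, s, list(a), function(nd) {
    g <- nd$grad
    ad_accum(nd$parents[[1L]], s * sweep(g, 2L, colSums(g * s)))
  })
}

# Collapse rows: n x c -> 1 x c column sums.
ad_sum_rows <- function(tape, a) {
  ad_node(tape, matrix(colSums(a$value), 1L), list(a), function(nd) {
    p <- nd$parents[[1L]]
    ad_accum(p, matrix(nd$grad, nrow(p$value), ncol(p$value), byrow = TRUE))
  })
}

# Collapse columns: n x c -> n x 1 row sums.
ad_sum_cols <- function(tape, a) {
  ad_node(tape, matrix(rowSums(a$value), ncol = 1L), list(a), function(nd) {
    p <- nd$parents[[1L]]
    ad_accum(p, matrix(nd$grad, nrow(p$value), ncol(p$value)))
  })
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(nd) {
    ad_accum(nd$parents[[1L]], t(nd$grad))
  })
}

ad_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad[, seq_len(na), drop = FALSE])
    ad_accum(nd$parents[[2L]], nd$grad[, -seq_len(na), drop = FALSE])
  })
}

ad_rows <- function(tape, a, idx) {
  force(idx)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(nd) {
    p <- nd$parents[[1L]]
    g <- matrix(0, nrow(p$value), ncol(p$value))
    for (r in seq_along(idx)) {
      g[idx[r], ] <- g[idx[r], ] + nd$grad[r, ]
    }
    ad_accum(p, g)
  })
}

# Embedding lookup: ids == 0 (padding) map to the zero vector and receive no
# gradient; ids >= 1 index rows of the embedding matrix W.
ad_embed <- function(tape, W, ids) {
  force(ids)
  v <- matrix(0, length(ids), ncol(W$value))
  nz <- which(ids > 0L)
  if (length(nz)) v[nz, ] <- W$value[ids[nz], , drop = FALSE]
  ad_node(tape, v, list(W), function(nd) {
    p <- nd$parents[[1L]]
    g <- matrix(0, nrow(p$value), ncol(p$value))
    for (r in nz) {
      g[ids[r], ] <- g[ids[r], ] + nd$grad[r, ]
    }
    ad_accum(p, g)
  })
}

# im2col for stride-1 valid 1D convolution: X (L x C) -> (L-k+1) x (k*C),
# column block j holding X shifted by j-1 rows.
ad_im2col <- function(tape, a, k) {
  X <- a$value
  L <- nrow(X); C <- ncol(X)
  Lo <- L - k + 1L
  stopifnot(Lo >= 1L)
  v <- matrix(0, Lo, k * C)
  for (j in seq_len(k)) {
    v[, ((j - 1L) * C + 1L):(j * C)] <- X[j:(Lo + j - 1L), , drop = FALSE]
  }
  ad_node(tape, v, list(a), function(nd) {
    g <- matrix(0, L, C)
    for (j in seq_len(k)) {
      g[j:(Lo + j - 1L), ] <- g[j:(Lo + j - 1L), ] +
        nd$grad[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    }
    ad_accum(nd$parents[[1L]], g)
  })
}

# Outer sum: u (n x 1), v (m x 1) -> n x m matrix u_i + v_j (GAT scores).
ad_outer_sum <- function(tape, u, v) {
  n <- nrow(u$value); m <- nrow(v$value)
  val <- matrix(u$value, n, m) + matrix(v$value, n, m, byrow = TRUE)
  ad_node(tape, val, list(u, v), function(nd) {
    ad_accum(nd$parents[[1L]], matrix(rowSums(nd$grad), ncol = 1L))
    ad_accum(nd$parents[[2L]], matrix(colSums(nd$grad), ncol = 1L))
  })
}

# Edge-network message passing (MPNN): for each directed edge e = (src w,
# dst v), interpret row e of `Arows` (n_e x d*d) as a column-major d x d
# matrix A_e and accumulate m[v, ] += A_e %*% h[w, ].
ad_edge_message <- function(tape, Arows, H, edges, n_atoms) {
  force(edges); force(n_atoms)
  d <- ncol(H$value)
  m <- matrix(0, n_atoms, d)
  ne <- nrow(edges)
  if (ne > 0L) {
    for (e in seq_len(ne)) {
      A <- matrix(Arows$value[e, ], d, d)
      m[edges[e, 2L], ] <- m[edges[e, 2L], ] + as.numeric(A %*% H$value[edges[e, 1L], ])
    }
  }
  ad_node(tape, m, list(Arows, H), function(nd) {
    pa <- nd$parents[[1L]]; ph <- nd$parents[[2L]]
    gA <- matrix(0, nrow(pa$value), ncol(pa$value))
    gH <- matrix(0, nrow(ph$value), ncol(ph$value))
    for (e in seq_len(ne)) {
      w <- edges[e, 1L]; v <- edges[e, 2L]
      A <- matrix(pa$value[e, ], d, d)
      gv <- nd$grad[v, ]
      gH[w, ] <- gH[w, ] + as.numeric(crossprod(A, gv))
      gA[e, ] <- gA[e, ] + as.numeric(outer(gv, ph$value[w, ]))
    }
    ad_accum(pa, gA)
    ad_accum(ph, gH)
  })
}

# Column-wise max pooling: n x c -> 1 x c; gradient routes to the first
# argmax row of each column.
ad_maxpool_cols <- function(tape, a) {
  X <- a$value
  idx <- max.col(t(X), ties.method = "first")
  v <- matrix(X[cbind(idx, seq_len(ncol(X)))], 1L)
  ad_node(tape, v, list(a), function(nd) {
    p <- nd$parents[[1L]]
    g <- matrix(0, nrow(p$value), ncol(p$value))
    g[cbind(idx, seq_len(ncol(g)))] <- nd$grad
    ad_accum(p, g)
  })
}

# Mean squared error over a list of scalar prediction nodes against a numeric
# truth vector; returns a scalar node.
ad_mse_loss <- function(tape, preds, truth) {
  stopifnot(length(preds) == length(truth))
  n <- length(preds)
  p <- vapply(preds, function(nd) nd$value[1L, 1L], numeric(1L))
  ad_node(tape, matrix(mean((p - truth)^2), 1L, 1L), preds, function(nd) {
    g <- nd$grad[1L, 1L]
    for (i in seq_len(n)) {
      ad_accum(nd$parents[[i]], matrix(2 * (p[i] - truth[i]) / n * g, 1L, 1L))
    }
  })
}

# Affine layer helper: relu/identity(X W + b).
ad_dense <- function(tape, x, W, b, activation = c("relu", "identity", "tanh",
                                                   "sigmoid")) {
  activation <- match.arg(activation)
  out <- ad_add_bias(tape, ad_matmul(tape, x, W), b)
  switch(activation,
         relu = ad_relu(tape, out),
         tanh = ad_tanh(tape, out),
         sigmoid = ad_sigmoid(tape, out),
         identity = out)
}
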