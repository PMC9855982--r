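# Model configuration and parameter initialization.

#' Model and training configuration
#'
#' Collects every tunable of the affinity model with its default. Defaults
#' follow the published training protocol of this model family: 1000 epochs
#' with early-stopping patience 30, batch size 32, Adam with learning rate
#' 5e-4 and weight decay 1e-5, embedding size 128, fully connected head
#' (1024, 512, 1), protein convolution kernel 8, dropout 0.1, and 2/3/5 as
#' the admissible GNN depths (default 3).
#'
#' @param variant GNN drug-encoder variant: one of `"GCN"`, `"GAT"`,
#'   `"GIN"`, `"MPNN"`, `"DMPNN"`.
#' @param gnn_layers Number of message-passing layers (2, 3 or 5).
#' @param embedding_size Shared embedding dimension `d` of atom rows,
#'   sub-sequence rows, and attended features.
#' @param gat_heads Attention head count for GAT (concatenated on hidden
#'   layers, averaged on the final layer).
#' @param kernel_size Protein convolution filter width (residues).
#' @param max_len Maximum protein length; longer sequences keep their
#'   N-terminal prefix, shorter ones are zero-padded.
#' @param prot_embed_dim Residue embedding dimension before convolution.
#' @param conv_channels Channel counts of the first two convolution layers;
#'   the third always outputs `embedding_size`.
#' @param fc_sizes Hidden sizes of the regression head (the final scalar
#'   layer is implicit).
#' @param dropout Dropout rate in the regression head (training only).
#' @param mpnn_edge_hidden Hidden width of the MPNN edge network.
#' @param epochs,batch_size,learning_rate,weight_decay,patience Training
#'   protocol settings (Adam).
#' @param seed Integer seed controlling weight initialization, data
#'   shuffling, and dropout.
#' @return A `dta_config` list.
#' @export
dta_config <- function(variant = c("GCN", "GAT", "GIN", "MPNN", "DMPNN"),
                       gnn_layers = 3L,
                       embedding_size = 128L,
                       gat_heads = 2L,
                       kernel_size = 8L,
                       max_len = 1000L,
                       prot_embed_dim = 128L,
                       conv_channels = c(32L, 64L),
                       fc_sizes = c(1024L, 512L),
                       dropout = 0.1,
                       mpnn_edge_hidden = 32L,
                       epochs = 1000L,
                       batch_size = 32L,
                       learning_rate = 5e-4,
                       weight_decay = 1e-5,
                       patience = 30L,
                       seed = 42L) {
  variant <- match.arg(variant)
  stopifnot(gnn_layers >= 1L, embedding_size >= 1L, kernel_size >= 1L,
            max_len >= 1L, length(conv_channels) == 2L,
            length(fc_sizes) == 2L, dropout >= 0, dropout < 1,
            epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            weight_decay >= 0, patience >= 1L, patience < epochs)
  if (variant == "GAT" && embedding_size %% gat_heads != 0L) {
    stop("embedding_size must be divisible by gat_heads for GAT")
  }
  ns <- max_len - 3L * (kernel_size - 1L)
  if (ns < 1L) {
    stop("kernel_size ", kernel_size, " leaves no valid convolution window ",
         "for max_len ", max_len)
  }
  structure(list(
    variant = variant, gnn_layers = as.integer(gnn_layers),
    embedding_size = as.integer(embedding_size),
    gat_heads = as.integer(gat_heads),
    kernel_size = as.integer(kernel_size), max_len = as.integer(max_len),
    prot_embed_dim = as.integer(prot_embed_dim),
    conv_channels = as.integer(conv_channels),
    fc_sizes = as.integer(fc_sizes), dropout = dropout,
    mpnn_edge_hidden = as.integer(mpnn_edge_hidden),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, weight_decay = weight_decay,
    patience = as.integer(patience), seed = as.integer(seed)),
    class = "dta_config")
}

# Glorot (Xavier) uniform initialization.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros_row <- function(n) matrix(0, 1L, n)

# Initialize all weights as a flat named list of matrices. Reproducible from
# config$seed.
init_dta_params <- function(config, vocab_size) {
  set.seed(config$seed)
  d <- config$embedding_size
  p <- list()
  p[["drug.proj.W"]] <- glorot(78L, d)
  p[["drug.proj.b"]] <- zeros_row(d)
  for (l in seq_len(config$gnn_layers)) {
    pre <- sprintf("drug.l%d.", l)
    switch(config$variant,
      GCN = {
        p[[paste0(pre, "W")]] <- glorot(d, d)
        p[[paste0(pre, "b")]] <- zeros_row(d)
      },
      GAT = {
        K <- config$gat_heads
        dh <- if (l == config$gnn_layers) d else d %/% K
        for (k in seq_len(K)) {
          hp <- sprintf("%sh%d.", pre, k)
          p[[paste0(hp, "W")]] <- glorot(d, dh)
          p[[paste0(hp, "a1")]] <- glorot(dh, 1L)
          p[[paste0(hp, "a2")]] <- glorot(dh, 1L)
        }
      },
      GIN = {
        for (part in c("msg", "upd")) {
          p[[sprintf("%s%s.W1", pre, part)]] <- glorot(d, d)
          p[[sprintf("%s%s.b1", pre, part)]] <- zeros_row(d)
          p[[sprintf("%s%s.W2", pre, part)]] <- glorot(d, d)
          p[[sprintf("%s%s.b2", pre, part)]] <- zeros_row(d)
        }
      },
      MPNN = {
        he <- config$mpnn_edge_hidden
        p[[paste0(pre, "edge.W1")]] <- glorot(14L, he)
        p[[paste0(pre, "edge.b1")]] <- zeros_row(he)
        p[[paste0(pre, "edge.W2")]] <- glorot(he, d * d)
        p[[paste0(pre, "edge.b2")]] <- zeros_row(d * d)
        for (g in c("r", "z", "n")) {
          p[[sprintf("%sgru.Wi%s", pre, g)]] <- glorot(d, d)
          p[[sprintf("%sgru.Wh%s", pre, g)]] <- glorot(d, d)
          p[[sprintf("%sgru.bi%s", pre, g)]] <- zeros_row(d)
          p[[sprintf("%sgru.bh%s", pre, g)]] <- zeros_row(d)
        }
      },
      DMPNN = {
        p[[paste0(pre, "Wm")]] <- glorot(d, d)
        p[[paste0(pre, "bm")]] <- zeros_row(d)
      })
  }
  if (config$variant == "DMPNN") {
    p[["drug.init.W"]] <- glorot(d + 14L, d)
    p[["drug.init.b"]] <- zeros_row(d)
    p[["drug.out.W"]] <- glorot(d, d)
    p[["drug.out.b"]] <- zeros_row(d)
  }
  pe <- config$prot_embed_dim
  k <- config$kernel_size
  ch <- c(pe, config$conv_channels, d)
  p[["prot.embed"]] <- glorot(vocab_size, pe)
  for (l in 1:3) {
    p[[sprintf("prot.conv%d.W", l)]] <- glorot(k * ch[l], ch[l + 1L])
    p[[sprintf("prot.conv%d.b", l)]] <- zeros_row(ch[l + 1L])
  }
  sizes <- c(2L * d, config$fc_sizes, 1L)
  for (l in 1:3) {
    p[[sprintf("head.fc%d.W", l)]] <- glorot(sizes[l], sizes[l + 1L])
    p[[sprintf("head.fc%d.b", l)]] <- zeros_row(sizes[l + 1L])
  }
  p
}

# Wrap every parameter matrix as a leaf node on `tape`; returns named list of
# nodes. Gradients accumulate on the leaves across all forwards on the tape.
params_to_nodes <- function(tape, params) {
  lapply(params, function(m) ad_leaf(tape, m))
}
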