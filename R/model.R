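# The full affinity model: drug encoder + protein encoder + interaction
# module + regression head, with a prepared-sample pipeline shared by
# training, prediction and attention export.

#' Construct an affinity model
#'
#' Initializes all weights (seeded from `config$seed`) for the given residue
#' vocabulary. The vocabulary travels with the model so that train- and
#' test-time encodings agree; it is serialized alongside the weights by
#' [dta_save()].
#'
#' @param config A [dta_config()].
#' @param vocab Named integer residue mapping from [build_vocab()].
#' @return A `dta_model`: list with `config`, `vocab`, and flat parameter
#'   list `params`.
#' @export
dta_model <- function(config = dta_config(), vocab) {
  stopifnot(inherits(config, "dta_config"), is.numeric(vocab),
            length(vocab) >= 1L, !is.null(names(vocab)))
  params <- init_dta_params(config, vocab_size = length(vocab))
  structure(list(config = config, vocab = vocab, params = params),
            class = "dta_model")
}

#' @export
print.dta_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1L)))
  cat("<dta_model> variant ", x$config$variant, ", ", x$config$gnn_layers,
      " GNN layers, d = ", x$config$embedding_size, ", ", np,
      " parameters, vocabulary size ", length(x$vocab), "\n", sep = "")
  invisible(x)
}

#' Prepare (SMILES, sequence) pairs for the model
#'
#' Parses the distinct SMILES into cached molecular graphs and encodes the
#' distinct sequences once, then assembles one sample per row.
#'
#' @param model A `dta_model`.
#' @param data Data frame with columns `smiles` and `sequence`, optionally
#'   `affinity` and id columns.
#' @return List of samples; each holds `graph`, `tokens`, and `affinity`
#'   (NA if absent).
#' @export
dta_prepare <- function(model, data) {
  stopifnot(inherits(model, "dta_model"),
            all(c("smiles", "sequence") %in% names(data)))
  usmi <- unique(data$smiles)
  graphs <- smiles_to_graphs(usmi)
  graphs <- lapply(graphs, prepare_graph)
  names(graphs) <- usmi
  useq <- unique(data$sequence)
  toks <- lapply(useq, function(s) {
    encode_sequence(s, model$vocab, model$config$max_len)$tokens
  })
  names(toks) <- useq
  aff <- if ("affinity" %in% names(data)) data$affinity else rep(NA_real_, nrow(data))
  lapply(seq_len(nrow(data)), function(i) {
    list(graph = graphs[[data$smiles[i]]],
         tokens = toks[[data$sequence[i]]],
         affinity = aff[i])
  })
}

# Forward pass for one prepared sample on a tape. Returns the interaction
# list (nodes). `dropout_masks` enables training-mode dropout.
model_forward <- function(tape, model_pnodes, config, sample,
                          dropout_masks = NULL, ablation = FALSE) {
  D <- drug_encoder_forward(tape, sample$graph, model_pnodes, config)
  S <- protein_encoder_forward(tape, sample$tokens, model_pnodes, config)
  if (ablation) {
    list(pred = ablation_forward(tape, D, S, model_pnodes, dropout_masks),
         D = D, S = S)
  } else {
    out <- interaction_forward(tape, D, S, model_pnodes, dropout_masks)
    out$D <- D; out$S <- S
    out
  }
}

new_dropout_masks <- function(config) {
  if (config$dropout <= 0) return(NULL)
  keep <- 1 - config$dropout
  lapply(config$fc_sizes, function(n) {
    matrix(stats::rbinom(n, 1L, keep) / keep, 1L)
  })
}

#' Predict binding affinities
#'
#' @param object A `dta_model`.
#' @param data Data frame with `smiles` and `sequence` columns, or a list of
#'   prepared samples from [dta_prepare()].
#' @param ablation Use the max-pool concatenation head instead of the
#'   attention interaction.
#' @param ... Unused.
#' @return Numeric vector of predicted pKd values.
#' @export
predict.dta_model <- function(object, data, ablation = FALSE, ...) {
  samples <- if (is.data.frame(data)) dta_prepare(object, data) else data
  vapply(samples, function(sm) {
    tape <- ad_tape()
    pn <- params_to_nodes(tape, object$params)
    model_forward(tape, pn, object$config, sm, ablation = ablation)$pred$value[1L, 1L]
  }, numeric(1L))
}

#' Compute interaction tensors for one drug-target pair
#'
#' Runs the full model on a single (SMILES, sequence) pair and returns the
#' relation matrix `R`, the significance matrices `a` (columns sum to 1) and
#' `s` (rows sum to 1), the attended features, and the predicted affinity.
#'
#' @param model A `dta_model`.
#' @param smiles Compound SMILES string.
#' @param sequence Protein residue string.
#' @return List with `R`, `a`, `s`, `D_doubleprime`, `P_doubleprime`,
#'   `drug_feature`, `protein_feature`, `prediction`, and the parsed `graph`.
#' @export
interaction_tensors <- function(model, smiles, sequence) {
  sm <- dta_prepare(model, data.frame(smiles = smiles, sequence = sequence,
                                      stringsAsFactors = FALSE))[[1L]]
  tape <- ad_tape()
  pn <- params_to_nodes(tape, model$params)
  out <- model_forward(tape, pn, model$config, sm)
  list(R = out$R$value, a = out$a$value, s = out$s$value,
       D_doubleprime = out$D_doubleprime$value,
       P_doubleprime = out$P_doubleprime$value,
       drug_feature = out$drug_feature$value,
       protein_feature = out$protein_feature$value,
       prediction = out$pred$value[1L, 1L],
       graph = sm$graph)
}
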