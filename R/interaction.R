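# Local-to-global interaction module: the relation matrix between atom rows
# and sub-sequence rows, its two softmax normalisations (the significance
# matrices used both for attention pooling and interpretation), the attended
# drug/protein features, and the regression head.
#
# Conventions: D is Na x d (atoms), S is Ns x d (sub-sequences),
# R = D S' is Na x Ns. The substructure significance a normalizes each
# column of R over atoms; the sub-sequence significance s normalizes each
# row over sub-sequences.

#' Relation matrix between drug atoms and protein sub-sequences
#'
#' `R[i, j]` is the dot product of atom row `i` of `D` with sub-sequence row
#' `j` of `S`.
#'
#' @param D Drug embedding matrix (`Na x d`) or a `drug_embedding`.
#' @param S Protein embedding matrix (`Ns x d`) or a `protein_embedding`.
#' @return Numeric `Na x Ns` matrix.
#' @export
relation_matrix <- function(D, S) {
  D <- embedding_values(D); S <- embedding_values(S)
  if (ncol(D) != ncol(S)) {
    stop("embedding dimension mismatch: D has ", ncol(D), " columns, S has ",
         ncol(S))
  }
  tcrossprod(D, S)
}

embedding_values <- function(x) {
  if (inherits(x, c("drug_embedding", "protein_embedding"))) x$values
  else as.matrix(x)
}

# Numerically stabilized softmax over matrix rows / columns.
softmax_rows <- function(R) {
  mx <- apply(R, 1L, max)
  e <- exp(R - mx)
  e / rowSums(e)
}

softmax_cols <- function(R) t(softmax_rows(t(R)))

#' Substructure significance matrix
#'
#' Atom-wise softmax of the relation matrix: each column `j` is normalized
#' over atoms, so `a[i, j]` is atom `i`'s importance to sub-sequence `j` and
#' every column sums to 1.
#'
#' @param R Relation matrix (`Na x Ns`), finite.
#' @return `Na x Ns` matrix with columns summing to 1.
#' @export
substructure_significance <- function(R) {
  R <- as.matrix(R)
  stopifnot(all(is.finite(R)))
  softmax_cols(R)
}

#' Sub-sequence significance matrix
#'
#' Sub-sequence-wise softmax of the relation matrix: each row `i` is
#' normalized over sub-sequences, so `s[i, j]` is sub-sequence `j`'s
#' importance to atom `i` and every row sums to 1.
#'
#' @param R Relation matrix (`Na x Ns`), finite.
#' @return `Na x Ns` matrix with rows summing to 1.
#' @export
subsequence_significance <- function(R) {
  R <- as.matrix(R)
  stopifnot(all(is.finite(R)))
  softmax_rows(R)
}

#' Attended drug feature
#'
#' For each sub-sequence `j`, column `a_j` weights the atom rows of `D`;
#' summing over atoms gives the 1 x d vector `d''(j)`, stacked into
#' `D'' (Ns x d)`; `drug_feature` is the sum of `D''` over sub-sequences.
#' Algebraically `D'' = a' D` and `drug_feature = (sum_j a_j)' D`.
#'
#' @param a Substructure significance matrix (`Na x Ns`, columns sum to 1).
#' @param D Drug embedding matrix (`Na x d`).
#' @return List with `D_doubleprime` (`Ns x d`) and `drug_feature` (`1 x d`).
#' @export
attended_drug_feature <- function(a, D) {
  a <- as.matrix(a); D <- embedding_values(D)
  if (nrow(a) != nrow(D)) {
    stop("a has ", nrow(a), " atom rows but D has ", nrow(D))
  }
  Dpp <- crossprod(a, D)
  list(D_doubleprime = Dpp,
       drug_feature = matrix(colSums(Dpp), 1L))
}

#' Attended protein feature
#'
#' For each atom `i`, row `s_i` weights the sub-sequence rows of `S`; summing
#' over sub-sequences gives `p''(i)`, stacked into `P'' (Na x d)`;
#' `protein_feature` is the sum of `P''` over atoms. Algebraically
#' `P'' = s S` and `protein_feature = (sum_i s_i) S`.
#'
#' @param s Sub-sequence significance matrix (`Na x Ns`, rows sum to 1).
#' @param S Protein embedding matrix (`Ns x d`).
#' @return List with `P_doubleprime` (`Na x d`) and `protein_feature`
#'   (`1 x d`).
#' @export
attended_protein_feature <- function(s, S) {
  s <- as.matrix(s); S <- embedding_values(S)
  if (ncol(s) != nrow(S)) {
    stop("s has ", ncol(s), " sub-sequence columns but S has ", nrow(S), " rows")
  }
  Ppp <- s %*% S
  list(P_doubleprime = Ppp,
       protein_feature = matrix(colSums(Ppp), 1L))
}

# Regression head on the tape: concat -> (1024) relu dropout -> (512) relu
# dropout -> scalar. Dropout masks are supplied by the caller (NULL at
# inference).
head_forward <- function(tape, drug_feat, prot_feat, pnodes,
                         dropout_masks = NULL) {
  z <- ad_cbind(tape, drug_feat, prot_feat)
  for (l in 1:3) {
    z <- ad_add_bias(tape,
      ad_matmul(tape, z, pnodes[[sprintf("head.fc%d.W", l)]]),
      pnodes[[sprintf("head.fc%d.b", l)]])
    if (l < 3L) {
      z <- ad_relu(tape, z)
      if (!is.null(dropout_masks)) {
        z <- ad_mul_const(tape, z, dropout_masks[[l]])
      }
    }
  }
  z
}

# Full interaction forward on the tape given embedding nodes D and S.
interaction_forward <- function(tape, D, S, pnodes, dropout_masks = NULL) {
  R <- ad_matmul(tape, D, ad_transpose(tape, S))
  a <- ad_softmax_cols(tape, R)
  s <- ad_softmax_rows(tape, R)
  Dpp <- ad_matmul(tape, ad_transpose(tape, a), D)
  drug_feat <- ad_sum_rows(tape, Dpp)
  Ppp <- ad_matmul(tape, s, S)
  prot_feat <- ad_sum_rows(tape, Ppp)
  pred <- head_forward(tape, drug_feat, prot_feat, pnodes, dropout_masks)
  list(R = R, a = a, s = s, D_doubleprime = Dpp, P_doubleprime = Ppp,
       drug_feature = drug_feat, protein_feature = prot_feat, pred = pred)
}

# Ablation forward: column-wise max pooling of D and S, concatenation, same
# FC stack (no attention).
ablation_forward <- function(tape, D, S, pnodes, dropout_masks = NULL) {
  head_forward(tape, ad_maxpool_cols(tape, D), ad_maxpool_cols(tape, S),
               pnodes, dropout_masks)
}

#' Predict affinity from attended features
#'
#' Concatenates the two 1 x d attended features and applies the fully
#' connected stack (1024, 512, 1) with ReLU; dropout is inactive (inference
#' mode).
#'
#' @param drug_feature,protein_feature Numeric `1 x d` vectors.
#' @param head Named list holding `head.fc1.W`, `head.fc1.b`, ...,
#'   `head.fc3.b` (a full model parameter list works).
#' @return Scalar predicted affinity (pKd).
#' @export
predict_affinity <- function(drug_feature, protein_feature, head) {
  tape <- ad_tape()
  pn <- params_to_nodes(tape, head[grep("^head\\.", names(head), value = TRUE)])
  df <- ad_leaf(tape, matrix(as.numeric(drug_feature), 1L))
  pf <- ad_leaf(tape, matrix(as.numeric(protein_feature), 1L))
  head_forward(tape, df, pf, pn)$value[1L, 1L]
}

#' Ablation head: max-pooled concatenation
#'
#' The no-attention baseline: column-wise max over the atom rows of `D` and
#' over the sub-sequence rows of `S`, concatenated and passed through the
#' same fully connected stack.
#'
#' @param D Drug embedding matrix (`Na x d`).
#' @param S Protein embedding matrix (`Ns x d`).
#' @param head Parameter list as in [predict_affinity()].
#' @return Scalar predicted affinity (pKd).
#' @export
ablation_concat_head <- function(D, S, head) {
  D <- embedding_values(D); S <- embedding_values(S)
  tape <- ad_tape()
  pn <- params_to_nodes(tape, head[grep("^head\\.", names(head), value = TRUE)])
  ablation_forward(tape, ad_leaf(tape, D), ad_leaf(tape, S), pn)$value[1L, 1L]
}
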