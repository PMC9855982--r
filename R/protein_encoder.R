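# Protein sub-sequence embedding matrix S (Ns x d): residue embedding lookup
# followed by three consecutive stride-1 "valid" 1D convolutions with ReLU.
# With kernel width k and input length L, Ns = L - 3 (k - 1): each output row
# summarizes a window of 3 (k - 1) + 1 consecutive residues (22 for k = 8).

# Tape version used by the full model.
protein_encoder_forward <- function(tape, tokens, pnodes, config) {
  L <- length(tokens)
  k <- config$kernel_size
  if (L - 3L * (k - 1L) < 1L) {
    stop("kernel_size ", k, " exceeds the remaining length of a ", L,
         "-token sequence after three valid convolutions")
  }
  h <- ad_embed(tape, pnodes[["prot.embed"]], tokens)
  for (l in 1:3) {
    h <- ad_relu(tape, ad_add_bias(tape,
      ad_matmul(tape, ad_im2col(tape, h, k),
                pnodes[[sprintf("prot.conv%d.W", l)]]),
      pnodes[[sprintf("prot.conv%d.b", l)]]))
  }
  h
}

#' Encode a protein as a sub-sequence embedding matrix
#'
#' Embeds the integer token vector (padding id 0 maps to the zero vector) and
#' applies three stride-1 valid 1D convolutions with ReLU, producing the
#' protein embedding matrix `S` with one row per sub-sequence window.
#'
#' @param protein An `encoded_protein` from [encode_sequence()], or a bare
#'   integer token vector.
#' @param params Flat named parameter list; if `NULL`, fresh seeded
#'   parameters are drawn from `config`.
#' @param config A `dta_config`. Its `max_len` must match the token length.
#' @return A `protein_embedding` object: list with `values`
#'   (`Ns x d`, `Ns = max_len - 3 (kernel_size - 1)`), `kernel_size`, and
#'   `num_conv_layers = 3`.
#' @export
encode_protein <- function(protein, params = NULL, config = dta_config()) {
  tokens <- if (inherits(protein, "encoded_protein")) protein$tokens else protein
  stopifnot(is.numeric(tokens), all(tokens >= 0L))
  if (is.null(params)) {
    params <- init_dta_params(config, vocab_size = max(25L, max(tokens) + 1L))
  }
  tape <- ad_tape()
  pnodes <- params_to_nodes(tape, params)
  cfg <- config
  cfg$max_len <- length(tokens)
  s <- protein_encoder_forward(tape, as.integer(tokens), pnodes, cfg)
  structure(list(values = s$value, kernel_size = config$kernel_size,
                 num_conv_layers = 3L), class = "protein_embedding")
}

#' Receptive field of one sub-sequence row
#'
#' Maps sub-sequence index `j` (1-based row of the protein embedding matrix)
#' to the residue window it summarizes, in 0-based half-open coordinates on
#' the (possibly truncated) encoded sequence.
#'
#' @param j Sub-sequence row index (1-based).
#' @param kernel_size Convolution kernel width.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
subseq_window <- function(j, kernel_size = 8L) {
  width <- 3L * (kernel_size - 1L) + 1L
  c(start = j - 1L, end = j - 1L + width)
}
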