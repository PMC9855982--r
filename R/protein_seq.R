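# Integer encoding of protein amino-acid sequences.
#
# Sequences are mapped to fixed-length integer vectors: each residue symbol
# gets a positive integer id (0 is reserved for padding), sequences longer
# than the maximum length keep their N-terminal prefix, and shorter ones are
# zero-padded on the right.

#' Build a residue vocabulary from observed sequences
#'
#' Every distinct residue symbol observed across `sequences` receives a
#' unique integer id starting at 1, assigned in sorted symbol order so the
#' mapping is reproducible from the data alone. Id 0 is reserved for
#' padding. Kinase-style datasets typically yield 20 (canonical residues)
#' or 21 (one extra symbol such as X) entries.
#'
#' @param sequences Character vector of residue strings.
#' @return Named integer vector mapping residue symbol to id.
#' @examples
#' build_vocab(c("ACD", "CDE"))
#' @export
build_vocab <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0L ||
      all(!nzchar(sequences))) {
    stop("no sequences supplied to build_vocab()")
  }
  symbols <- sort(unique(unlist(strsplit(sequences, ""), use.names = FALSE)))
  stats::setNames(seq_along(symbols), symbols)
}

#' Encode a residue sequence as a fixed-length integer vector
#'
#' The first `min(nchar(seq), max_len)` positions hold vocabulary ids; any
#' remainder is zero padding. Sequences longer than `max_len` are truncated
#' to their N-terminal prefix.
#'
#' @param seq A single residue string.
#' @param vocab Named integer mapping from [build_vocab()].
#' @param max_len Fixed output length (default 1000).
#' @return An `encoded_protein` object: list with integer `tokens` of length
#'   `max_len`, `original_length`, and the `vocab` used.
#' @examples
#' v <- build_vocab("ACDEFGHIKLMNPQRSTVWY")
#' p <- encode_sequence("MKV", v, max_len = 6)
#' p$tokens
#' @export
encode_sequence <- function(seq, vocab, max_len = 1000L) {
  stopifnot(is.character(seq), length(seq) == 1L, max_len >= 1L)
  if (is.na(seq) || !nzchar(seq)) stop("empty protein sequence")
  chars <- strsplit(seq, "")[[1L]]
  ids <- unname(vocab[chars])
  if (anyNA(ids)) {
    i <- which(is.na(ids))[1L]
    stop("unknown residue symbol '", chars[i], "' at position ", i)
  }
  n <- length(ids)
  keep <- min(n, max_len)
  tokens <- integer(max_len)
  tokens[seq_len(keep)] <- ids[seq_len(keep)]
  structure(list(tokens = tokens, original_length = n, vocab = vocab),
            class = "encoded_protein")
}

#' Decode tokens back to a residue string
#'
#' Inverse of [encode_sequence()] restricted to the retained (non-padding)
#' prefix.
#'
#' @param encoded An `encoded_protein` object.
#' @return Character string of the retained residues.
#' @export
decode_sequence <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_protein"))
  ids <- encoded$tokens[encoded$tokens > 0L]
  paste(names(encoded$vocab)[ids], collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a plain named
#' character vector (record id, first whitespace-delimited word, to
#' sequence).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- vapply(strsplit(names(aa), "[[:space:]]+"), `[[`, character(1L), 1L)
  out
}

#' @export
print.encoded_protein <- function(x, ...) {
  cat("<encoded_protein> length ", x$original_length, ", encoded to ",
      length(x$tokens), " tokens (", sum(x$tokens > 0L), " non-padding)\n",
      sep = "")
  invisible(x)
}
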