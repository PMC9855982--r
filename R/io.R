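# Dataset and model input/output: delimited dataset files, YAML/JSON
# configuration, model archives (weights + config + vocabulary in one JSON
# file), attention exports, and the synthetic-dataset writer.

required_columns <- c("compound_id", "smiles", "protein_id", "sequence",
                      "affinity")

#' Read a drug-target affinity dataset
#'
#' Reads a delimited (TSV/CSV, autodetected) file with header columns
#' `compound_id`, `smiles`, `protein_id`, `sequence`, `affinity`. Affinities
#' are pKd by default; raw dissociation constants in nM require
#' `scale = "Kd_nM"` and are converted with [pkd_transform()] (an explicit
#' flag prevents silent unit errors). Rows failing validation (empty
#' sequence, malformed SMILES, non-finite affinity) abort by default or are
#' dropped with a warning naming line numbers under `on_invalid = "skip"`.
#'
#' @param path Dataset file path.
#' @param scale `"pKd"` (default) or `"Kd_nM"`.
#' @param on_invalid `"stop"` (default) or `"skip"`.
#' @return Data frame of validated records with pKd-scale `affinity`.
#' @export
read_dataset <- function(path, scale = c("pKd", "Kd_nM"),
                         on_invalid = c("stop", "skip")) {
  scale <- match.arg(scale)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(required_columns, names(df))
  if (length(missing)) {
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("compound_id", "smiles", "protein_id", "sequence")) {
    df[[col]] <- as.character(df[[col]])
  }
  bad <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$sequence[i]) || !nzchar(df$sequence[i])) {
      bad[i] <- "empty sequence"
    } else if (!is.finite(df$affinity[i])) {
      bad[i] <- "non-finite affinity"
    } else if (scale == "Kd_nM" && df$affinity[i] <= 0) {
      bad[i] <- "non-positive Kd"
    } else {
      err <- validate_smiles(df$smiles[i])
      if (!is.null(err)) bad[i] <- paste0("bad SMILES (", err, ")")
    }
  }
  invalid <- which(nzchar(bad))
  if (length(invalid)) {
    desc <- paste(sprintf("line %d: %s", invalid + 1L, bad[invalid]),
                  collapse = "; ")
    if (on_invalid == "stop") {
      stop(length(invalid), " invalid row(s): ", desc)
    }
    warning("skipped ", length(invalid), " invalid row(s): ", desc)
    df <- df[-invalid, , drop = FALSE]
  }
  if (scale == "Kd_nM") df$affinity <- pkd_transform(df$affinity)
  rownames(df) <- NULL
  df
}

#' Write a drug-target affinity dataset as TSV
#'
#' @param data Data frame with the standard columns (see [read_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(all(required_columns %in% names(data)))
  data.table::fwrite(data[, required_columns], path, sep = "\t")
  invisible(path)
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Writes `<stem>.tsv` (the dataset) and `<stem>.truth.json` (per-pair
#' fragment/motif flags, motif positions, compound/protein tables, and the
#' generating spec, seed included).
#'
#' @param ds A `synthetic_dta` from [generate_dta()].
#' @param stem Output path stem.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_synthetic_dta <- function(ds, stem) {
  stopifnot(inherits(ds, "synthetic_dta"))
  data_path <- paste0(stem, ".tsv")
  truth_path <- paste0(stem, ".truth.json")
  write_dataset(ds$data, data_path)
  jsonlite::write_json(
    list(spec = unclass(ds$spec), truth = ds$truth,
         compounds = ds$compounds, proteins = ds$proteins),
    truth_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(data = data_path, truth = truth_path))
}

#' Save a model archive
#'
#' Serializes weights, configuration and residue vocabulary into one JSON
#' archive so train-time encodings are reproducible at load time.
#'
#' @param model A `dta_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
dta_save <- function(model, path) {
  stopifnot(inherits(model, "dta_model"))
  ser <- list(
    format = "dtattn-model-1",
    config = unclass(model$config),
    vocab = as.list(model$vocab),
    params = lapply(model$params, function(m) {
      list(dim = dim(m), data = as.numeric(m))
    }),
    history = model$history,
    best_epoch = model$best_epoch)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load a model archive written by [dta_save()]
#'
#' @param path Archive path.
#' @return A `dta_model`.
#' @export
dta_load <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "dtattn-model-1")) {
    stop("not a model archive: ", path)
  }
  config <- do.call(dta_config, ser$config[setdiff(names(ser$config), NULL)])
  vocab <- unlist(ser$vocab)
  model <- structure(list(
    config = config,
    vocab = stats::setNames(as.integer(vocab), names(vocab)),
    params = lapply(ser$params, function(p) {
      matrix(p$data, p$dim[1L], p$dim[2L])
    })), class = "dta_model")
  if (!is.null(ser$history)) model$history <- ser$history
  if (!is.null(ser$best_epoch)) model$best_epoch <- ser$best_epoch
  model
}

#' Export attention maps for one drug-target pair
#'
#' Writes a TSV with one summary row per atom and one per sub-sequence
#' window for each significance matrix: atom rows carry the atom's mean
#' significance across sub-sequences, window rows the window's mean
#' significance across atoms. Sub-sequence window coordinates are 0-based,
#' half-open, on the truncated (at most `max_len` residues) sequence; window
#' `j` covers residues `[j - 1, j - 1 + 3 (k - 1) + 1)`.
#'
#' @param model A `dta_model`.
#' @param smiles Compound SMILES.
#' @param sequence Protein residue string.
#' @param path Output TSV path.
#' @param full Also append one row per (atom, window) cell of each matrix.
#' @return The interaction tensors, invisibly.
#' @export
export_attention <- function(model, smiles, sequence, path, full = FALSE) {
  it <- interaction_tensors(model, smiles, sequence)
  k <- model$config$kernel_size
  na <- nrow(it$a); ns <- ncol(it$a)
  win <- t(vapply(seq_len(ns), subseq_window, integer(2L), kernel_size = k))
  elements <- it$graph$atoms$element
  atom_rows <- function(mat, label) {
    data.frame(matrix_name = label, summary_over = "atom",
               atom_index = seq_len(na) - 1L,
               smiles_atom_map = elements,
               subseq_start = NA_integer_, subseq_end = NA_integer_,
               score = rowMeans(mat), stringsAsFactors = FALSE)
  }
  win_rows <- function(mat, label) {
    data.frame(matrix_name = label, summary_over = "subsequence",
               atom_index = NA_integer_, smiles_atom_map = NA_character_,
               subseq_start = win[, 1L], subseq_end = win[, 2L],
               score = colMeans(mat), stringsAsFactors = FALSE)
  }
  out <- rbind(atom_rows(it$a, "substructure_significance"),
               win_rows(it$a, "substructure_significance"),
               atom_rows(it$s, "subsequence_significance"),
               win_rows(it$s, "subsequence_significance"))
  if (full) {
    cells <- expand.grid(atom = seq_len(na), j = seq_len(ns))
    out <- rbind(out,
      data.frame(matrix_name = "substructure_significance_full",
                 summary_over = "cell",
                 atom_index = cells$atom - 1L,
                 smiles_atom_map = elements[cells$atom],
                 subseq_start = win[cells$j, 1L],
                 subseq_end = win[cells$j, 2L],
                 score = it$a[cbind(cells$atom, cells$j)],
                 stringsAsFactors = FALSE),
      data.frame(matrix_name = "subsequence_significance_full",
                 summary_over = "cell",
                 atom_index = cells$atom - 1L,
                 smiles_atom_map = elements[cells$atom],
                 subseq_start = win[cells$j, 1L],
                 subseq_end = win[cells$j, 2L],
                 score = it$s[cbind(cells$atom, cells$j)],
                 stringsAsFactors = FALSE))
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(it)
}

#' Read a model configuration file
#'
#' YAML or JSON (by extension); keys are [dta_config()] arguments.
#'
#' @param path Config file path.
#' @return A `dta_config`.
#' @export
read_dta_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("config must be .yaml/.yml/.json: ", path))
  unknown <- setdiff(names(vals), names(formals(dta_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(dta_config, vals)
}

# Small stable content hash (FNV-1a, 32-bit) for run logging.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h a double (can exceed 2^31)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split to stay inside double precision
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format the two halves separately
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
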