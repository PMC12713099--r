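# Structure-informed protein representations for POIs and E3 ligases, behind
# a pluggable embedder interface. A real protein language model can be
# plugged in when its weights are available locally; the deterministic stub
# makes the whole pipeline runnable offline and is what the tests use.

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.with_local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Load protein records from a FASTA file
#'
#' @param fasta_path path to a FASTA file keyed by accession (first word of
#'   each header).
#' @param ids accessions to load; all must be present.
#' @return list of `ProteinRecord` objects (uniprot_id, sequence) in request
#'   order. Non-standard residues are mapped to X. Duplicate FASTA entries
#'   use the first occurrence with a warning.
#' @export
load_sequences <- function(fasta_path, ids) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(fasta_path)
  keys <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(keys)) {
    warning("duplicate FASTA accession(s): ",
            paste(unique(keys[duplicated(keys)]), collapse = ", "),
            "; using first occurrence")
    aa <- aa[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  missing <- setdiff(ids, keys)
  if (length(missing) > 0L) {
    stop("accession(s) absent from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(ids, function(id) {
    protein_record(id, as.character(aa[[match(id, keys)]]))
  })
}

#' Construct a protein record
#'
#' @param uniprot_id accession string.
#' @param sequence amino-acid string; letters outside the standard 20-letter
#'   alphabet are mapped to X.
#' @return object of class `ProteinRecord`.
#' @export
protein_record <- function(uniprot_id, sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[!chars %in% .AA_ALPHABET] <- "X"
  structure(list(uniprot_id = uniprot_id,
                 sequence = paste(chars, collapse = "")),
            class = "ProteinRecord")
}

#' Deterministic stub protein embedder
#'
#' Maps each residue letter (position-independently) to a fixed
#' pseudo-random 1280-vector derived from (seed, letter). Identical sequences
#' give identical matrices across runs and platforms, so the full pipeline is
#' runnable and testable with no model weights. Implements the embedder
#' interface: `dim()` returning the embedding width and `tokens(sequence)`
#' returning a length x dim matrix.
#'
#' @param seed integer seed.
#' @param dim embedding width (default 1280, matching the protein language
#'   model the adapter is sized for).
#' @return object of class `Embedder`.
#' @export
stub_embedder <- function(seed = 0L, dim = 1280L) {
  letter_vecs <- new.env(parent = emptyenv())
  letter_vec <- function(ch) {
    v <- letter_vecs[[ch]]
    if (is.null(v)) {
      sub_seed <- (abs(as.integer(seed)) %% 100000L) * 20011L +
        utf8ToInt(ch) * 7919L
      v <- .with_local_rng(sub_seed %% 2147483647L, stats::rnorm(dim))
      letter_vecs[[ch]] <- v
    }
    v
  }
  structure(
    list(
      name = sprintf("stub-%d", as.integer(seed)),
      dim = function() dim,
      tokens = function(sequence) {
        chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
        out <- matrix(0, nrow = length(chars), ncol = dim)
        for (i in seq_along(chars)) out[i, ] <- letter_vec(chars[i])
        out
      }
    ),
    class = "Embedder")
}

#' Embed a protein record
#'
#' The sequence is truncated to `max_len` residues (default 1022) before
#' embedding. In token mode the per-residue matrix is returned; in pooled
#' mode the row-mean vector (the "averaged" sequence representation).
#'
#' @param record a `ProteinRecord`.
#' @param embedder an `Embedder` (see [stub_embedder()]).
#' @param mode "token" (per-residue, default) or "pooled".
#' @param max_len maximum residues fed to the embedder (default 1022).
#' @return object of class `ProteinEmbedding` with `token_matrix` (alpha x
#'   theta), `pooled_vector` (theta), `mode`, `uniprot_id`.
#' @export
embed_protein <- function(record, embedder, mode = c("token", "pooled"),
                          max_len = 1022L) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "ProteinRecord"), inherits(embedder, "Embedder"))
  seq <- record$sequence
  if (nchar(seq) > max_len) seq <- substr(seq, 1L, max_len)
  tok <- tryCatch(
    embedder$tokens(seq),
    error = function(e) {
      stop("embedder failed on accession ", record$uniprot_id, ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (!is.matrix(tok) || ncol(tok) != embedder$dim()) {
    stop("embedder returned a malformed matrix for accession ",
         record$uniprot_id, call. = FALSE)
  }
  structure(
    list(token_matrix = tok,
         pooled_vector = colMeans(tok),
         mode = mode,
         uniprot_id = record$uniprot_id),
    class = "ProteinEmbedding")
}

#' Initialize adapter weights
#'
#' Two linear layers with bias mapping the embedder width down to the hidden
#' protein representation; separate instances are used for the POI and the
#' E3 ligase. Default widths [128, 64].
#'
#' @param input_dim embedder width (default 1280).
#' @param hidden widths of the two layers (default c(128, 64)).
#' @param seed integer seed for initialization.
#' @return object of class `AdapterWeights`: list(W1, b1, W2, b2).
#' @export
adapter_weights <- function(input_dim = 1280L, hidden = c(128L, 64L),
                            seed = 0L) {
  stopifnot(length(hidden) == 2L, all(hidden > 0L))
  .with_local_rng(seed, {
    W1 <- matrix(stats::rnorm(hidden[1L] * input_dim, sd = sqrt(2 / input_dim)),
                 nrow = hidden[1L])
    W2 <- matrix(stats::rnorm(hidden[2L] * hidden[1L],
                              sd = sqrt(2 / hidden[1L])),
                 nrow = hidden[2L])
    structure(list(W1 = W1, b1 = numeric(hidden[1L]),
                   W2 = W2, b2 = numeric(hidden[2L])),
              class = "AdapterWeights")
  })
}

#' Apply the adapter to a protein embedding
#'
#' Per-column application of linear -> activation -> linear -> activation.
#' In token mode the output columns are indexed by residue (D x alpha); in
#' pooled mode a single column (D x 1).
#'
#' @param embedding a `ProteinEmbedding`.
#' @param weights an `AdapterWeights`.
#' @param activation activation function (default ReLU).
#' @return D x alpha numeric matrix.
#' @export
adapt <- function(embedding, weights,
                  activation = function(x) pmax(x, 0)) {
  stopifnot(inherits(embedding, "ProteinEmbedding"),
            inherits(weights, "AdapterWeights"))
  X <- if (embedding$mode == "pooled") {
    matrix(embedding$pooled_vector, ncol = 1L)
  } else {
    t(embedding$token_matrix)
  }
  if (nrow(X) != ncol(weights$W1)) {
    stop("embedding width ", nrow(X), " does not match adapter input ",
         ncol(weights$W1), call. = FALSE)
  }
  H <- activation(weights$W1 %*% X + weights$b1)
  activation(weights$W2 %*% H + weights$b2)
}
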