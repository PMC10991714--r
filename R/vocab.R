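# Tokenization: residue / gene / isotype vocabularies and instance encoding.

#' Build the model vocabulary from a repertoire
#'
#' Maps the 20 amino acids to token indices 1..20 and reserves PAD (21) and
#' MASK (22) tokens; V and J gene names each get an index with a trailing
#' out-of-vocabulary (OOV) slot for genes unseen at training time. The PAD
#' token is pinned to the zero embedding vector, which doubles as the
#' integrated-gradients baseline.
#'
#' @param table Repertoire table supplying the observed V/J gene sets, or
#'   NULL together with explicit `v_genes` / `j_genes`.
#' @param v_genes,j_genes Optional explicit gene name vectors.
#' @return A `bcr_vocab` list.
#' @export
build_vocab <- function(table = NULL, v_genes = NULL, j_genes = NULL) {
  v_genes <- sort(unique(v_genes %||% table$v_gene))
  j_genes <- sort(unique(j_genes %||% table$j_gene))
  structure(list(
    residues = stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET),
    pad_idx = 21L,
    mask_idx = 22L,
    n_residue_tokens = 22L,
    v_levels = v_genes,
    j_levels = j_genes,
    v_oov = length(v_genes) + 1L,
    j_oov = length(j_genes) + 1L,
    iso_levels = ISOTYPE_LEVELS
  ), class = "bcr_vocab")
}

v_index <- function(vocab, v) {
  i <- match(v, vocab$v_levels)
  i[is.na(i)] <- vocab$v_oov
  i
}
j_index <- function(vocab, j) {
  i <- match(j, vocab$j_levels)
  i[is.na(i)] <- vocab$j_oov
  i
}

#' Encode a batch of records into model-ready index arrays
#'
#' Tokenizes HCDR3 sequences into fixed-length index rows (right-padded with
#' PAD to `max_len`) plus categorical indices for isotype, V and J. With
#' `mask = TRUE` a single non-PAD position per sequence is replaced by the
#' MASK token and its original residue stored as the auxiliary-task target;
#' the mask positions are a deterministic function of the seed.
#'
#' @param table Repertoire table (lengths must lie within `[8, max_len]`).
#' @param vocab A [build_vocab()] vocabulary.
#' @param max_len Maximum sequence length (default 25).
#' @param mask Mask one residue per sequence for the auxiliary task?
#' @param seed Seed for mask-position sampling (required when `mask = TRUE`).
#' @return A `bcr_encoded` list: `tokens` (n x max_len integer matrix),
#'   `lengths`, `iso_idx`, `v_idx`, `j_idx`, optional `y` (subset index),
#'   `mask_pos`, `aux_target`.
#' @export
encode_records <- function(table, vocab, max_len = 25L, mask = FALSE, seed = NULL) {
  n <- nrow(table)
  lens <- nchar(table$hcdr3_aa)
  if (any(lens < 8 | lens > max_len)) {
    stop("HCDR3 length out of range [8, ", max_len, "]; apply filter_hcdr3_length first")
  }
  tokens <- matrix(vocab$pad_idx, nrow = n, ncol = max_len)
  for (i in seq_len(n)) {
    ch <- strsplit(table$hcdr3_aa[i], "", fixed = TRUE)[[1]]
    idx <- vocab$residues[ch]
    if (anyNA(idx)) {
      bad <- ch[is.na(idx)][1]
      stop("residue outside the 20-letter alphabet: '", bad,
           "' in ", table$sequence_id[i])
    }
    tokens[i, seq_along(idx)] <- idx
  }
  enc <- list(tokens = tokens, lengths = lens,
              iso_idx = match(table$isotype, vocab$iso_levels),
              v_idx = v_index(vocab, table$v_gene),
              j_idx = j_index(vocab, table$j_gene),
              sequence_id = table$sequence_id)
  if (anyNA(enc$iso_idx)) stop("unknown isotype in table")
  if ("subset" %in% names(table) && !anyNA(table$subset)) {
    enc$y <- match(table$subset, SUBSET_LEVELS)
  }
  if (mask) {
    if (is.null(seed)) stop("mask = TRUE requires a seed")
    mask_pos <- with_seed(seed, vapply(lens, function(L) sample.int(L, 1L), integer(1)))
    aux_target <- tokens[cbind(seq_len(n), mask_pos)]
    tokens[cbind(seq_len(n), mask_pos)] <- vocab$mask_idx
    enc$tokens <- tokens
    enc$mask_pos <- mask_pos
    enc$aux_target <- aux_target
  }
  structure(enc, class = "bcr_encoded")
}

# Subset an encoded batch by row indices.
encoded_slice <- function(enc, idx) {
  out <- list(tokens = enc$tokens[idx, , drop = FALSE],
              lengths = enc$lengths[idx],
              iso_idx = enc$iso_idx[idx],
              v_idx = enc$v_idx[idx],
              j_idx = enc$j_idx[idx],
              sequence_id = enc$sequence_id[idx])
  for (f in c("y", "mask_pos", "aux_target")) {
    if (!is.null(enc[[f]])) out[[f]] <- enc[[f]][idx]
  }
  structure(out, class = "bcr_encoded")
}

encoded_n <- function(enc) nrow(enc$tokens)
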