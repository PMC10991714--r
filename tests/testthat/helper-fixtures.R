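# Shared fixtures. Expensive objects (trained models) are built once per
# test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# A small repertoire table built by hand, no randomness.
toy_table <- function() {
  bcr_repertoire(tibble::tibble(
    sequence_id = sprintf("s%02d", 1:6),
    hcdr3_aa = c("CARDYWGQGTLV", "CARDYWGQGTLV", "CAKEGYSSGWYF",
                 "CARDPRSAVAGF", "CTRDLRGAFDIW", "CARGYSSSWYEG"),
    v_gene = c("IGHV1-2", "IGHV1-2", "IGHV3-23", "IGHV3-23", "IGHV4-34", "IGHV1-2"),
    j_gene = c("IGHJ4", "IGHJ4", "IGHJ6", "IGHJ6", "IGHJ4", "IGHJ4"),
    isotype = c("IgM", "IgG", "IgG", "IgA", "IgM", "IgD"),
    subset = c("naive", "memory", "memory", "asc", "naive", "memory"),
    shm_count = c(0L, 5L, 7L, 9L, 1L, 4L)))
}

# Study conditions for learnability checks: strong subset motifs on top of
# the subset-conditional isotype / SHM structure.
motif_spec <- function(n = 2000L, seed = 11L, prob = 0.9) {
  synthetic_spec(
    n_records = n,
    motifs = list(naive = list(motif = "NAW", position = 5, prob = prob),
                  memory = list(motif = "MKY", position = 5, prob = prob),
                  asc = list(motif = "DEH", position = 5, prob = prob)),
    seed = seed)
}

# Desk-scale model configuration used throughout the tests.
small_config <- function(seed = 1L) {
  bcr_config(residue_embed_dim = 8L, lstm_hidden = 16L,
             cnn_channels = c(32L, 32L, 32L), cat_embed_dim = 8L,
             mlp_widths = c(64L, 32L), seed = seed)
}

tiny_config <- function(seed = 2L) {
  bcr_config(residue_embed_dim = 4L, lstm_hidden = 5L,
             cnn_channels = c(6L, 6L, 6L), cat_embed_dim = 3L,
             mlp_widths = c(8L, 7L), seed = seed)
}

# A model trained once on motif-coded data; reused by attribution and
# mutagenesis tests.
trained_fixture <- function() {
  if (is.null(.fixtures$trained)) {
    tab <- simulate_repertoire(motif_spec(n = 800L, seed = 21L))
    model <- train(tab, small_config(seed = 3L), lr = 3e-3, batch_size = 128L,
                   epochs = 6L, seed = 7L)
    .fixtures$trained <- list(model = model, table = tab)
  }
  .fixtures$trained
}

# Independent Spearman implementation (rank the two vectors by brute force,
# then Pearson on the ranks) used as an oracle against stats::cor.
spearman_oracle <- function(x, y) {
  brute_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      smaller <- sum(v < v[i])
      ties <- sum(v == v[i])
      smaller + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- brute_rank(x); ry <- brute_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
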