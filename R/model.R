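# The subset-classifier model object and its user-facing forward interface.

#' Create an untrained subset-classifier model
#'
#' Initializes model parameters for the given configuration and vocabulary.
#' The PAD token embedding is pinned to the zero vector and never updated:
#' it is both the padding representation and the integrated-gradients
#' baseline.
#'
#' @param config A [bcr_config()].
#' @param vocab A [build_vocab()] vocabulary.
#' @return A `bcr_model` list with elements `config`, `vocab`, `params`,
#'   `history`.
#' @export
bcr_model <- function(config, vocab) {
  structure(list(config = config, vocab = vocab,
                 params = init_params(config, vocab),
                 history = NULL),
            class = "bcr_model")
}

#' Run the model forward on a batch of encoded instances
#'
#' Inference-mode forward pass (dropout disabled): returns the class
#' probabilities, predicted labels, penultimate-layer embeddings and the
#' auxiliary masked-residue distribution. Output for each instance is
#' independent of batch composition and order.
#'
#' @param model A `bcr_model`.
#' @param enc A [encode_records()] batch (or a repertoire table, which is
#'   encoded on the fly).
#' @return List with `probs` (n x 3, columns naive/memory/asc), `label`,
#'   `penult`, `aux_probs`.
#' @export
model_forward <- function(model, enc) {
  if (inherits(enc, "data.frame")) {
    enc <- encode_records(enc, model$vocab, max_len = model$config$max_len)
  }
  emb <- embed_batch(model$params, enc, model$config$max_len)
  out <- nn_forward(model$params, model$config, emb, train = FALSE)
  colnames(out$probs) <- SUBSET_LEVELS
  list(probs = out$probs,
       label = SUBSET_LEVELS[max.col(out$probs, ties.method = "first")],
       penult = out$penult,
       aux_probs = out$aux_probs)
}

#' Predict B-cell subsets for a repertoire table
#'
#' @param object A trained `bcr_model`.
#' @param table Repertoire table.
#' @param ... Unused.
#' @return The table with columns `p_naive`, `p_memory`, `p_asc` and
#'   `predicted_subset` appended.
#' @export
predict.bcr_model <- function(object, table, ...) {
  out <- model_forward(object, table)
  table$p_naive <- out$probs[, "naive"]
  table$p_memory <- out$probs[, "memory"]
  table$p_asc <- out$probs[, "asc"]
  table$predicted_subset <- out$label
  table
}

#' @export
print.bcr_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<bcr_model> ", np, " parameters; classes: ",
      paste(SUBSET_LEVELS, collapse = "/"), "\n", sep = "")
  if (!is.null(x$history)) {
    cat("  trained ", nrow(x$history), " epochs; final val accuracy ",
        round(utils::tail(x$history$val_accuracy, 1), 3), "\n", sep = "")
  }
  invisible(x)
}

#' Combined classification + masked-residue loss
#'
#' Cross-entropy of the subset head plus `aux_weight` times the
#' cross-entropy of the auxiliary masked-residue head, both averaged over
#' the batch (the auxiliary term over masked instances; it is 0 when no
#' instance is masked).
#'
#' @param probs n x 3 subset probability matrix.
#' @param y Integer vector of true subset indices (1..3).
#' @param aux_probs Optional n x 20 auxiliary distribution matrix.
#' @param aux_target Optional integer vector of masked-residue token
#'   indices; NA for unmasked instances.
#' @param aux_weight Auxiliary-loss scale, default 0.05.
#' @return Scalar loss.
#' @export
total_loss <- function(probs, y, aux_probs = NULL, aux_target = NULL,
                       aux_weight = 0.05) {
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(seq_along(y), y)] + eps))
  if (!is.null(aux_target) && !is.null(aux_probs)) {
    masked <- which(!is.na(aux_target))
    if (length(masked) > 0) {
      loss <- loss + aux_weight *
        -mean(log(aux_probs[cbind(masked, aux_target[masked])] + eps))
    }
  }
  loss
}

#' Save a model checkpoint
#'
#' The checkpoint embeds the configuration and vocabulary alongside the
#' weights, so it is self-contained.
#'
#' @param model A `bcr_model`.
#' @param path File path (RDS).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File path written by [save_model()].
#' @return The `bcr_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "bcr_model")) stop("not a bcr_model checkpoint: ", path)
  m
}
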