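# Training loop, cross-validation, fine-tuning and evaluation summaries.

# One gradient step on an encoded mini-batch; returns updated model pieces
# and the batch loss. Masking/aux is active only when the batch carries
# aux_target and aux_weight > 0.
train_step <- function(params, config, vocab, enc, opt_state, lr,
                       aux_weight, dropout_seed) {
  emb <- embed_batch(params, enc, config$max_len)
  out <- nn_forward(params, config, emb, train = TRUE,
                    dropout_seed = dropout_seed, need_cache = TRUE)
  n <- encoded_n(enc)
  onehot <- matrix(0, n, config$n_classes)
  onehot[cbind(seq_len(n), enc$y)] <- 1
  dLogits <- (out$probs - onehot) / n
  dAux <- NULL
  aux_loss <- 0
  if (!is.null(enc$aux_target) && aux_weight > 0) {
    masked <- which(!is.na(enc$aux_target))
    if (length(masked) > 0) {
      oh <- matrix(0, n, config$aux_vocab_size)
      oh[cbind(masked, enc$aux_target[masked])] <- 1
      dAux <- matrix(0, n, config$aux_vocab_size)
      dAux[masked, ] <- (out$aux_probs[masked, , drop = FALSE] -
                           oh[masked, , drop = FALSE]) *
        (aux_weight / length(masked))
      aux_loss <- -mean(log(out$aux_probs[cbind(masked, enc$aux_target[masked])] + 1e-12))
    }
  }
  loss <- total_loss(out$probs, enc$y, out$aux_probs, enc$aux_target,
                     aux_weight = if (is.null(dAux)) 0 else aux_weight)
  back <- nn_backward(params, config, out$cache, dLogits, dAux)
  grads <- c(back$grads, scatter_embedding_grads(params, vocab, enc, back))
  upd <- adam_step(params, grads, opt_state, lr)
  list(params = upd$params, opt_state = upd$state, loss = loss,
       aux_loss = aux_loss,
       accuracy = mean(max.col(out$probs, ties.method = "first") == enc$y))
}

eval_encoded <- function(params, config, enc) {
  emb <- embed_batch(params, enc, config$max_len)
  out <- nn_forward(params, config, emb, train = FALSE)
  list(loss = total_loss(out$probs, enc$y),
       accuracy = mean(max.col(out$probs, ties.method = "first") == enc$y),
       pred = max.col(out$probs, ties.method = "first"))
}

run_training <- function(model, table, lr, batch_size, epochs, seed,
                         validation, val_fraction, mask, aux_weight,
                         patience, verbose) {
  config <- model$config; vocab <- model$vocab
  if (!"subset" %in% names(table) || anyNA(table$subset)) {
    stop("training requires subset labels on every record")
  }
  if (length(unique(table$subset)) < config$n_classes) {
    stop("every subset (", paste(SUBSET_LEVELS, collapse = ", "),
         ") must be present in the training data")
  }
  if (is.null(validation)) {
    n <- nrow(table)
    n_val <- max(1L, floor(val_fraction * n))
    idx <- with_seed(seed + 17L, sample.int(n))
    validation <- table[idx[seq_len(n_val)], , drop = FALSE]
    table <- table[idx[(n_val + 1):n], , drop = FALSE]
  }
  enc_train <- encode_records(table, vocab, config$max_len,
                              mask = mask, seed = seed)
  enc_val <- encode_records(validation, vocab, config$max_len)
  params <- model$params
  opt_state <- adam_init(params)
  hist <- list()
  best <- list(params = params, val_loss = Inf, epoch = 0L)
  n <- encoded_n(enc_train)
  for (epoch in seq_len(epochs)) {
    perm <- with_seed(seed + epoch, sample.int(n))
    starts <- seq(1, n, by = batch_size)
    ep_loss <- 0; ep_aux <- 0; ep_acc <- 0; wsum <- 0
    for (bi in seq_along(starts)) {
      rows <- perm[starts[bi]:min(starts[bi] + batch_size - 1, n)]
      batch <- encoded_slice(enc_train, rows)
      st <- train_step(params, config, vocab, batch, opt_state, lr,
                       aux_weight, dropout_seed = seed * 1000L + epoch * 100L + bi)
      params <- st$params; opt_state <- st$opt_state
      w <- length(rows)
      ep_loss <- ep_loss + st$loss * w
      ep_aux <- ep_aux + st$aux_loss * w
      ep_acc <- ep_acc + st$accuracy * w
      wsum <- wsum + w
    }
    ev <- eval_encoded(params, config, enc_val)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / wsum, train_accuracy = ep_acc / wsum,
      aux_loss = ep_aux / wsum,
      val_loss = ev$loss, val_accuracy = ev$accuracy)
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, ep_loss / wsum, ep_acc / wsum, ev$loss, ev$accuracy))
    }
    if (ev$loss < best$val_loss - 1e-9) {
      best <- list(params = params, val_loss = ev$loss, epoch = epoch)
    } else if (epoch - best$epoch >= patience) {
      break
    }
  }
  model$params <- if (epochs > 0) best$params else params
  model$history <- if (length(hist) > 0) dplyr::bind_rows(hist) else
    tibble::tibble(epoch = integer(), lr = numeric(), train_loss = numeric(),
                   train_accuracy = numeric(), aux_loss = numeric(),
                   val_loss = numeric(), val_accuracy = numeric())
  model
}

#' Train the subset classifier
#'
#' Mini-batch Adam training of the full model with the masked-residue
#' auxiliary task (one residue masked per sequence, auxiliary cross-entropy
#' scaled by `aux_weight`). A best-validation-loss checkpoint is kept and
#' returned; early stopping halts training when validation loss has not
#' improved for `patience` epochs. Deterministic given the seed.
#'
#' @param table Labeled, preprocessed repertoire table (length-filtered and
#'   cross-subset deduplicated). All three subsets must be present.
#' @param config A [bcr_config()]; default configuration if omitted.
#' @param lr Learning rate (default `1e-4`).
#' @param batch_size Mini-batch size (default 1024).
#' @param epochs Maximum epochs (default 30). `epochs = 0` returns the
#'   freshly initialized model unchanged.
#' @param seed Integer seed covering initialization, masking, shuffling.
#' @param validation Optional held-out repertoire table; when NULL a
#'   fraction `val_fraction` of `table` is split off (seeded).
#' @param val_fraction Validation fraction when `validation` is NULL.
#' @param aux_weight Auxiliary-loss scale (default 0.05); 0 disables masking.
#' @param patience Early-stopping patience in epochs.
#' @param vocab Optional pre-built vocabulary (defaults to the table's).
#' @param verbose Print per-epoch metrics?
#' @return A trained `bcr_model` with a `history` tibble (per-epoch train /
#'   validation loss and accuracy, auxiliary loss, learning rate).
#' @export
train <- function(table, config = bcr_config(), lr = 1e-4, batch_size = 1024L,
                  epochs = 30L, seed = 1L, validation = NULL,
                  val_fraction = 0.1, aux_weight = 0.05, patience = 5L,
                  vocab = NULL, verbose = FALSE) {
  vocab <- vocab %||% build_vocab(table)
  config$seed <- as.integer(seed)
  model <- bcr_model(config, vocab)
  if (epochs == 0) return(model)
  run_training(model, table, lr = lr, batch_size = batch_size,
               epochs = epochs, seed = seed, validation = validation,
               val_fraction = val_fraction, mask = aux_weight > 0,
               aux_weight = aux_weight, patience = patience, verbose = verbose)
}

#' Fine-tune a trained model on a new repertoire (transfer learning)
#'
#' Continues training from the supplied weights at `lr_scale` times the base
#' learning rate, with the masked-residue auxiliary task disabled (its loss
#' contribution is exactly 0 every step) and no layer frozen: every
#' parameter receives gradient updates. The architecture is unchanged.
#' Disease-specific and chronological transfer are this same operation run
#' on different tables.
#'
#' @param model A trained `bcr_model`.
#' @param table Labeled repertoire table to adapt to.
#' @param base_lr Base learning rate the model was trained with.
#' @param lr_scale Learning-rate multiplier, default 0.1.
#' @param epochs,batch_size,seed,validation,val_fraction,patience,verbose
#'   As in [train()].
#' @return The fine-tuned `bcr_model` (history reflects the fine-tuning run).
#' @export
fine_tune <- function(model, table, base_lr = 1e-4, lr_scale = 0.1,
                      epochs = 10L, batch_size = 1024L, seed = 1L,
                      validation = NULL, val_fraction = 0.1, patience = 5L,
                      verbose = FALSE) {
  if (!inherits(model, "bcr_model")) stop("model must be a bcr_model")
  if (epochs == 0 || lr_scale == 0) {
    if (lr_scale == 0 && epochs > 0) {
      # zero learning rate: run nothing, weights are by definition unchanged
      return(model)
    }
    return(model)
  }
  run_training(model, table, lr = base_lr * lr_scale,
               batch_size = batch_size, epochs = epochs, seed = seed,
               validation = validation, val_fraction = val_fraction,
               mask = FALSE, aux_weight = 0, patience = patience,
               verbose = verbose)
}

# Stratified fold assignment: records are shuffled within subset, the
# subsets concatenated, and folds dealt in one continuous round-robin —
# per-subset counts and total fold sizes both differ by at most one.
stratified_folds <- function(subset, k, seed) {
  ord <- unlist(lapply(SUBSET_LEVELS, function(ss) {
    rows <- which(subset == ss)
    if (length(rows) == 0) return(integer(0))
    with_seed(seed + match(ss, SUBSET_LEVELS), sample(rows))
  }))
  fold <- integer(length(subset))
  fold[ord] <- rep_len(seq_len(k), length(ord))
  fold
}

#' k-fold cross-validation of the classifier
#'
#' Folds are stratified by subset; each record appears in exactly one test
#' fold. Reports per-fold accuracy, their mean and standard deviation, and
#' the confusion matrix pooled over all test folds.
#'
#' @param table Labeled repertoire table.
#' @param config A [bcr_config()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param ... Passed to [train()] (`lr`, `epochs`, `batch_size`, ...).
#' @return List: `fold_metrics` tibble, `mean_accuracy`, `sd_accuracy`,
#'   `confusion` (3 x 3, rows = true subset), `fold` assignment vector.
#' @export
cross_validate <- function(table, config = bcr_config(), k = 5L, seed = 1L, ...) {
  n <- nrow(table)
  if (k > n) stop("k must not exceed the number of records")
  vocab <- build_vocab(table)
  fold <- stratified_folds(table$subset, k, seed)
  confusion <- matrix(0L, 3, 3, dimnames = list(true = SUBSET_LEVELS,
                                                predicted = SUBSET_LEVELS))
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    m <- train(tr, config = config, seed = seed + f, vocab = vocab, ...)
    ev <- evaluate(m, te)
    accs[f] <- ev$accuracy
    confusion <- confusion + ev$confusion
  }
  list(fold_metrics = tibble::tibble(fold = seq_len(k), accuracy = accs),
       mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs),
       confusion = confusion, fold = fold)
}

#' Evaluate a model on a labeled repertoire
#'
#' @param model A trained `bcr_model`.
#' @param table Labeled repertoire table.
#' @return List: `accuracy`; `confusion` (3 x 3, rows indexed by true subset
#'   in the order naive/memory/asc, row sums equal true class counts);
#'   `by_isotype` and `by_length` accuracy tibbles (lengths restricted to
#'   8–25 by construction).
#' @export
evaluate <- function(model, table) {
  if (!"subset" %in% names(table) || anyNA(table$subset)) {
    stop("evaluate requires subset labels")
  }
  out <- model_forward(model, table)
  truth <- factor(table$subset, levels = SUBSET_LEVELS)
  pred <- factor(out$label, levels = SUBSET_LEVELS)
  confusion <- table(true = truth, predicted = pred)
  acc <- mean(out$label == table$subset)
  by_iso <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(isotype = table$isotype,
                                   correct = out$label == table$subset),
                    .data$isotype),
    n = dplyr::n(), accuracy = mean(.data$correct), .groups = "drop")
  by_len <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(length = nchar(table$hcdr3_aa),
                                   correct = out$label == table$subset),
                    .data$length),
    n = dplyr::n(), accuracy = mean(.data$correct), .groups = "drop")
  list(accuracy = acc, confusion = unclass(confusion),
       by_isotype = by_iso, by_length = by_len)
}
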