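# Neural-network core: parameter initialization, forward pass and explicit
# backpropagation for the subset classifier. Written directly in base R
# matrix operations so that gradients with respect to the *input embeddings*
# (needed by integrated gradients) are available, not only parameter
# gradients. Sequence tensors are lists of T matrices (batch x dim), which
# keeps every operation a plain BLAS matmul and batch rows independent.

#' Model configuration
#'
#' Architecture hyper-parameters of the subset classifier. The sequence
#' branch is a learnable residue embedding, a 2-layer bidirectional LSTM and
#' a stack of 1-d convolutions with global max pooling; V/J/isotype enter
#' through categorical embeddings; the fused vector feeds a 3-layer MLP
#' (softmax over naive/memory/asc) and, during pre-training, an auxiliary
#' 20-way head predicting a masked residue.
#'
#' @param max_len Maximum HCDR3 length (fixed at 25).
#' @param residue_embed_dim Residue embedding width.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param lstm_layers Number of stacked bidirectional LSTM layers.
#' @param cnn_channels Integer vector of convolution output channels.
#' @param kernel_sizes Odd kernel sizes, same length as `cnn_channels`.
#' @param cat_embed_dim Embedding width shared by isotype, V and J features.
#' @param mlp_widths Hidden widths of the MLP; the second entry is the
#'   penultimate-layer embedding dimension.
#' @param n_classes Number of output classes (3).
#' @param dropout Dropout probability on the fused feature vector during
#'   training (0 disables).
#' @param seed Seed for parameter initialization.
#' @return A `bcr_config` list.
#' @export
bcr_config <- function(max_len = 25L, residue_embed_dim = 32L,
                       lstm_hidden = 64L, lstm_layers = 2L,
                       cnn_channels = c(128L, 128L, 128L),
                       kernel_sizes = c(3L, 3L, 3L),
                       cat_embed_dim = 16L,
                       mlp_widths = c(256L, 128L),
                       n_classes = 3L, dropout = 0, seed = 1L) {
  stopifnot(max_len == 25L, length(cnn_channels) == length(kernel_sizes),
            all(kernel_sizes %% 2 == 1), length(mlp_widths) == 2,
            residue_embed_dim > 0, lstm_hidden > 0, cat_embed_dim > 0,
            all(cnn_channels > 0), all(mlp_widths > 0))
  structure(list(max_len = as.integer(max_len),
                 residue_embed_dim = as.integer(residue_embed_dim),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 cnn_channels = as.integer(cnn_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 cat_embed_dim = as.integer(cat_embed_dim),
                 mlp_widths = as.integer(mlp_widths),
                 n_classes = as.integer(n_classes),
                 aux_vocab_size = 20L,
                 dropout = dropout, seed = as.integer(seed)),
            class = "bcr_config")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# Parameters live in a single flat named list of numeric arrays, which makes
# the optimizer and gradient bookkeeping a plain mapply over leaves.
init_params <- function(config, vocab) {
  de <- config$residue_embed_dim; h <- config$lstm_hidden
  dc <- config$cat_embed_dim
  with_seed(config$seed, {
    p <- list(
      E_res = matrix(stats::rnorm(vocab$n_residue_tokens * de, sd = 0.1),
                     vocab$n_residue_tokens, de),
      E_iso = matrix(stats::rnorm(length(vocab$iso_levels) * dc, sd = 0.1),
                     length(vocab$iso_levels), dc),
      E_v = matrix(stats::rnorm(vocab$v_oov * dc, sd = 0.1), vocab$v_oov, dc),
      E_j = matrix(stats::rnorm(vocab$j_oov * dc, sd = 0.1), vocab$j_oov, dc)
    )
    p$E_res[vocab$pad_idx, ] <- 0  # PAD pinned to the zero vector (IG baseline)
    din <- de
    for (L in seq_len(config$lstm_layers)) {
      for (dir in c("f", "b")) {
        key <- paste0("l", L, dir)
        b <- numeric(4 * h)
        b[(h + 1):(2 * h)] <- 1  # forget-gate bias
        p[[paste0(key, ".Wx")]] <- glorot(din, 4 * h)
        p[[paste0(key, ".Wh")]] <- glorot(h, 4 * h)
        p[[paste0(key, ".b")]] <- b
      }
      din <- 2 * h
    }
    cin <- 2 * h
    for (i in seq_along(config$cnn_channels)) {
      cout <- config$cnn_channels[i]
      for (o in seq_len(config$kernel_sizes[i])) {
        p[[paste0("cv", i, ".W", o)]] <- glorot(cin, cout) / config$kernel_sizes[i]
      }
      p[[paste0("cv", i, ".b")]] <- numeric(cout)
      cin <- cout
    }
    dcat <- cin + 3 * dc
    widths <- c(dcat, config$mlp_widths, config$n_classes)
    for (i in seq_len(length(widths) - 1)) {
      p[[paste0("mlp.W", i)]] <- glorot(widths[i], widths[i + 1])
      p[[paste0("mlp.b", i)]] <- numeric(widths[i + 1])
    }
    p$aux.W <- glorot(dcat, config$aux_vocab_size)
    p$aux.b <- numeric(config$aux_vocab_size)
    p
  })
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- LSTM (one direction) ----------------------------------------------

lstm_dir_forward <- function(X, Wx, Wh, b, reverse = FALSE) {
  TT <- length(X); B <- nrow(X[[1]]); h <- nrow(Wh)
  ord <- if (reverse) rev(seq_len(TT)) else seq_len(TT)
  h_prev <- matrix(0, B, h); c_prev <- matrix(0, B, h)
  H <- vector("list", TT); cache <- vector("list", TT)
  ih <- seq_len(h); fh <- h + ih; gh <- 2 * h + ih; oh <- 3 * h + ih
  for (t in ord) {
    z <- X[[t]] %*% Wx + h_prev %*% Wh + matrix(b, B, 4 * h, byrow = TRUE)
    i <- 1 / (1 + exp(-z[, ih, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, fh, drop = FALSE]))
    g <- tanh(z[, gh, drop = FALSE])
    o <- 1 / (1 + exp(-z[, oh, drop = FALSE]))
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    H[[t]] <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                       tc = tc, h_prev = h_prev)
    h_prev <- H[[t]]; c_prev <- c_t
  }
  list(H = H, cache = cache, ord = ord)
}

lstm_dir_backward <- function(dH, fwd, X, Wx, Wh) {
  TT <- length(X); B <- nrow(X[[1]]); h <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, h, 4 * h)
  db <- numeric(4 * h)
  dX <- vector("list", TT)
  dh_next <- matrix(0, B, h); dc_next <- matrix(0, B, h)
  ih <- seq_len(h)
  for (t in rev(fwd$ord)) {
    cc <- fwd$cache[[t]]
    dh <- dh_next + (dH[[t]] %||% 0)
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(X[[t]], dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- 1-d convolution, same padding --------------------------------------

conv_forward <- function(X, W, b) {
  TT <- length(X); B <- nrow(X[[1]]); cout <- ncol(W[[1]])
  k <- length(W); half <- (k - 1) %/% 2
  Y <- vector("list", TT)
  bias <- matrix(b, B, cout, byrow = TRUE)
  for (t in seq_len(TT)) {
    acc <- bias
    for (o in seq_len(k)) {
      src <- t + o - 1 - half
      if (src >= 1 && src <= TT) acc <- acc + X[[src]] %*% W[[o]]
    }
    Y[[t]] <- acc
  }
  Y
}

conv_backward <- function(dY, X, W) {
  TT <- length(X); k <- length(W); half <- (k - 1) %/% 2
  dW <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  db <- numeric(ncol(W[[1]]))
  dX <- lapply(X, function(x) matrix(0, nrow(x), nrow(W[[1]])))
  for (t in seq_len(TT)) {
    db <- db + colSums(dY[[t]])
    for (o in seq_len(k)) {
      src <- t + o - 1 - half
      if (src >= 1 && src <= TT) {
        dW[[o]] <- dW[[o]] + crossprod(X[[src]], dY[[t]])
        dX[[src]] <- dX[[src]] + dY[[t]] %*% t(W[[o]])
      }
    }
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- full forward -------------------------------------------------------

# Build input embeddings from an encoded batch.
embed_batch <- function(params, enc, max_len) {
  B <- nrow(enc$tokens)
  Eseq <- lapply(seq_len(max_len), function(t) {
    params$E_res[enc$tokens[, t], , drop = FALSE]
  })
  list(Eseq = Eseq,
       e_iso = params$E_iso[enc$iso_idx, , drop = FALSE],
       e_v = params$E_v[enc$v_idx, , drop = FALSE],
       e_j = params$E_j[enc$j_idx, , drop = FALSE])
}

# Forward pass from embeddings. `emb` is a list(Eseq, e_iso, e_v, e_j).
# Returns logits/probabilities, penultimate activations, auxiliary logits
# and (if need_cache) everything required by nn_backward.
nn_forward <- function(params, config, emb, train = FALSE, dropout_seed = NULL,
                       need_cache = FALSE) {
  TT <- config$max_len
  X <- emb$Eseq
  lstm_caches <- list()
  for (L in seq_len(config$lstm_layers)) {
    kf <- paste0("l", L, "f"); kb <- paste0("l", L, "b")
    fwd <- lstm_dir_forward(X, params[[paste0(kf, ".Wx")]],
                            params[[paste0(kf, ".Wh")]],
                            params[[paste0(kf, ".b")]], reverse = FALSE)
    bwd <- lstm_dir_forward(X, params[[paste0(kb, ".Wx")]],
                            params[[paste0(kb, ".Wh")]],
                            params[[paste0(kb, ".b")]], reverse = TRUE)
    H <- lapply(seq_len(TT), function(t) cbind(fwd$H[[t]], bwd$H[[t]]))
    lstm_caches[[L]] <- list(fwd = fwd, bwd = bwd, X = X)
    X <- H
  }
  conv_caches <- list()
  for (i in seq_along(config$cnn_channels)) {
    k <- config$kernel_sizes[i]
    W <- lapply(seq_len(k), function(o) params[[paste0("cv", i, ".W", o)]])
    pre <- conv_forward(X, W, params[[paste0("cv", i, ".b")]])
    act <- lapply(pre, function(z) pmax(z, 0))
    conv_caches[[i]] <- list(X = X, pre = pre)
    X <- act
  }
  # global max pool over positions
  B <- nrow(X[[1]]); C <- ncol(X[[1]])
  feat <- X[[1]]; argt <- matrix(1L, B, C)
  for (t in 2:TT) {
    better <- X[[t]] > feat
    feat[better] <- X[[t]][better]
    argt[better] <- t
  }
  fused <- cbind(feat, emb$e_iso, emb$e_v, emb$e_j)
  drop_mask <- NULL
  if (train && config$dropout > 0) {
    keep <- 1 - config$dropout
    drop_mask <- with_seed(dropout_seed %||% 0L,
                           matrix(stats::rbinom(length(fused), 1, keep) / keep,
                                  nrow(fused), ncol(fused)))
    fused <- fused * drop_mask
  }
  A1pre <- fused %*% params$mlp.W1 +
    matrix(params$mlp.b1, B, ncol(params$mlp.W1), byrow = TRUE)
  A1 <- pmax(A1pre, 0)
  A2pre <- A1 %*% params$mlp.W2 +
    matrix(params$mlp.b2, B, ncol(params$mlp.W2), byrow = TRUE)
  A2 <- pmax(A2pre, 0)
  logits <- A2 %*% params$mlp.W3 +
    matrix(params$mlp.b3, B, ncol(params$mlp.W3), byrow = TRUE)
  aux_logits <- fused %*% params$aux.W +
    matrix(params$aux.b, B, ncol(params$aux.W), byrow = TRUE)
  out <- list(logits = logits, probs = row_softmax(logits), penult = A2,
              aux_logits = aux_logits, aux_probs = row_softmax(aux_logits))
  if (need_cache) {
    out$cache <- list(emb = emb, lstm = lstm_caches, conv = conv_caches,
                      conv_out = X, argt = argt, feat = feat, fused = fused,
                      drop_mask = drop_mask,
                      A1 = A1, A1pre = A1pre, A2 = A2, A2pre = A2pre)
  }
  out
}

# Backward pass. dLogits (B x n_classes) and optional dAuxLogits (B x 20)
# are upstream gradients on the two heads. Returns parameter gradients (flat
# named list, embedding tables excluded) plus gradients on the input
# embeddings (dEseq list, d_iso, d_v, d_j).
nn_backward <- function(params, config, cache, dLogits, dAuxLogits = NULL) {
  TT <- config$max_len
  g <- list()
  B <- nrow(dLogits)
  g$mlp.W3 <- crossprod(cache$A2, dLogits)
  g$mlp.b3 <- colSums(dLogits)
  dA2 <- dLogits %*% t(params$mlp.W3)
  dA2 <- dA2 * (cache$A2pre > 0)
  g$mlp.W2 <- crossprod(cache$A1, dA2)
  g$mlp.b2 <- colSums(dA2)
  dA1 <- dA2 %*% t(params$mlp.W2)
  dA1 <- dA1 * (cache$A1pre > 0)
  g$mlp.W1 <- crossprod(cache$fused, dA1)
  g$mlp.b1 <- colSums(dA1)
  dFused <- dA1 %*% t(params$mlp.W1)
  if (!is.null(dAuxLogits)) {
    g$aux.W <- crossprod(cache$fused, dAuxLogits)
    g$aux.b <- colSums(dAuxLogits)
    dFused <- dFused + dAuxLogits %*% t(params$aux.W)
  } else {
    g$aux.W <- matrix(0, nrow(params$aux.W), ncol(params$aux.W))
    g$aux.b <- numeric(length(params$aux.b))
  }
  if (!is.null(cache$drop_mask)) dFused <- dFused * cache$drop_mask
  C <- ncol(cache$feat); dc <- config$cat_embed_dim
  dFeat <- dFused[, seq_len(C), drop = FALSE]
  d_iso <- dFused[, C + seq_len(dc), drop = FALSE]
  d_v <- dFused[, C + dc + seq_len(dc), drop = FALSE]
  d_j <- dFused[, C + 2 * dc + seq_len(dc), drop = FALSE]
  # unpool: route gradient to the argmax position per (row, channel)
  dX <- lapply(seq_len(TT), function(t) matrix(0, B, C))
  for (t in seq_len(TT)) {
    sel <- cache$argt == t
    if (any(sel)) {
      tmp <- matrix(0, B, C)
      tmp[sel] <- dFeat[sel]
      dX[[t]] <- tmp
    }
  }
  for (i in rev(seq_along(config$cnn_channels))) {
    cc <- cache$conv[[i]]
    dPre <- lapply(seq_len(TT), function(t) dX[[t]] * (cc$pre[[t]] > 0))
    k <- config$kernel_sizes[i]
    W <- lapply(seq_len(k), function(o) params[[paste0("cv", i, ".W", o)]])
    cb <- conv_backward(dPre, cc$X, W)
    for (o in seq_len(k)) g[[paste0("cv", i, ".W", o)]] <- cb$dW[[o]]
    g[[paste0("cv", i, ".b")]] <- cb$db
    dX <- cb$dX
  }
  h <- config$lstm_hidden
  for (L in rev(seq_len(config$lstm_layers))) {
    lc <- cache$lstm[[L]]
    dHf <- lapply(dX, function(m) m[, seq_len(h), drop = FALSE])
    dHb <- lapply(dX, function(m) m[, h + seq_len(h), drop = FALSE])
    kf <- paste0("l", L, "f"); kb <- paste0("l", L, "b")
    bf <- lstm_dir_backward(dHf, lc$fwd, lc$X, params[[paste0(kf, ".Wx")]],
                            params[[paste0(kf, ".Wh")]])
    bb <- lstm_dir_backward(dHb, lc$bwd, lc$X, params[[paste0(kb, ".Wx")]],
                            params[[paste0(kb, ".Wh")]])
    g[[paste0(kf, ".Wx")]] <- bf$dWx; g[[paste0(kf, ".Wh")]] <- bf$dWh
    g[[paste0(kf, ".b")]] <- bf$db
    g[[paste0(kb, ".Wx")]] <- bb$dWx; g[[paste0(kb, ".Wh")]] <- bb$dWh
    g[[paste0(kb, ".b")]] <- bb$db
    dX <- lapply(seq_len(TT), function(t) bf$dX[[t]] + bb$dX[[t]])
  }
  list(grads = g, dEseq = dX, d_iso = d_iso, d_v = d_v, d_j = d_j)
}

# Accumulate embedding-gradient rows into the embedding tables.
# The PAD row of E_res stays pinned at zero: its gradient is discarded.
scatter_embedding_grads <- function(params, vocab, enc, back) {
  g <- list(E_res = matrix(0, nrow(params$E_res), ncol(params$E_res)),
            E_iso = matrix(0, nrow(params$E_iso), ncol(params$E_iso)),
            E_v = matrix(0, nrow(params$E_v), ncol(params$E_v)),
            E_j = matrix(0, nrow(params$E_j), ncol(params$E_j)))
  for (t in seq_along(back$dEseq)) {
    rs <- rowsum(back$dEseq[[t]], group = enc$tokens[, t])
    idx <- as.integer(rownames(rs))
    g$E_res[idx, ] <- g$E_res[idx, ] + rs
  }
  g$E_res[vocab$pad_idx, ] <- 0
  for (nm in c("E_iso", "E_v", "E_j")) {
    key <- switch(nm, E_iso = enc$iso_idx, E_v = enc$v_idx, E_j = enc$j_idx)
    d <- switch(nm, E_iso = back$d_iso, E_v = back$d_v, E_j = back$d_j)
    rs <- rowsum(d, group = key)
    idx <- as.integer(rownames(rs))
    g[[nm]][idx, ] <- g[[nm]][idx, ] + rs
  }
  g
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gp <- grads[[nm]]
    if (is.null(gp)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gp
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gp^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
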