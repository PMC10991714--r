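# Integrated-gradients attribution over the 28 input features (25 residue
# slots incl. padding, isotype, V gene, J gene), high-IG feature selection
# and the downstream composition / positional / paratope summaries.

FEATURE_NAMES <- c(sprintf("pos%02d", 1:25), "isotype", "v_gene", "j_gene")

#' Generic path-integral attribution over arbitrary inputs
#'
#' Computes element-wise integrated gradients for a differentiable function
#' along the straight path from `baseline` to `V`:
#' `IG_k = (V_k - baseline_k) * (1/m) * sum_p grad_k(baseline + s_p (V - baseline))`
#' with `s_p = p/m` (right-endpoint Riemann rule, the default) or the
#' trapezoid rule. Useful as an independent cross-check of the batched
#' model-specific routine.
#'
#' @param V Named list of numeric arrays (the input point).
#' @param grad_fun Function taking a point (same structure as `V`) and
#'   returning the gradient of the scalar of interest, same structure.
#' @param m Number of interpolation steps (>= 1).
#' @param baseline Baseline point; defaults to all-zero.
#' @param scheme `"right"` (sum over p = 1..m) or `"trapezoid"`.
#' @return Element-wise IG values, same structure as `V`.
#' @export
ig_path_integral <- function(V, grad_fun, m, baseline = NULL,
                             scheme = c("right", "trapezoid")) {
  if (m < 1) stop("m must be >= 1")
  scheme <- match.arg(scheme)
  baseline <- baseline %||% lapply(V, function(x) x * 0)
  pts <- if (scheme == "right") seq_len(m) / m else (0:m) / m
  wts <- if (scheme == "right") rep(1 / m, m) else
    c(0.5, rep(1, m - 1), 0.5) / m
  acc <- lapply(V, function(x) x * 0)
  for (i in seq_along(pts)) {
    point <- mapply(function(v, b) b + pts[i] * (v - b), V, baseline,
                    SIMPLIFY = FALSE)
    g <- grad_fun(point)
    acc <- mapply(function(a, gi) a + wts[i] * gi, acc, g, SIMPLIFY = FALSE)
  }
  mapply(function(v, b, a) (v - b) * a, V, baseline, acc, SIMPLIFY = FALSE)
}

# Gradient of the target-class softmax probability w.r.t. the logits,
# one row per batch instance.
prob_grad_logits <- function(probs, target) {
  B <- nrow(probs); K <- ncol(probs)
  d <- -probs * probs[, target]
  d[, target] <- d[, target] + probs[, target]
  d
}

#' Integrated-gradients attribution for one record
#'
#' Attributes the model's output probability for `target_class` to every
#' input feature by integrating gradients along the straight path in
#' embedding space from the zero-vector baseline (the PAD embedding) to the
#' input, with a right-endpoint Riemann sum over `m` steps. Element-wise IG
#' values are averaged over each feature's embedding elements to give one
#' score per feature. All `m` path points are evaluated as a single batch.
#'
#' @param model A trained `bcr_model`.
#' @param record One-row repertoire table (or an encoded single instance).
#' @param m Number of interpolation steps (default 64).
#' @param target_class Attributed class; defaults to the predicted class.
#' @return A `bcr_attribution` list: `feature_scores` (named length-28
#'   vector), `elementwise` (per-feature element-wise IG), `m`, `baseline`,
#'   `target_class`, `probs`, `f_input`, `f_baseline`, `completeness_gap`,
#'   `sequence_length`, `sequence_id`.
#' @export
integrated_gradients <- function(model, record, m = 64L, target_class = NULL) {
  if (m < 1) stop("m must be >= 1")
  enc <- if (inherits(record, "bcr_encoded")) record else
    encode_records(record, model$vocab, model$config$max_len)
  if (encoded_n(enc) != 1) stop("integrated_gradients attributes one record at a time")
  params <- model$params; config <- model$config
  emb1 <- embed_batch(params, enc, config$max_len)
  emb0 <- list(Eseq = lapply(emb1$Eseq, function(x) x * 0),
               e_iso = emb1$e_iso * 0, e_v = emb1$e_v * 0, e_j = emb1$e_j * 0)
  base_out <- nn_forward(params, config, emb0)
  full_out <- nn_forward(params, config, emb1)
  probs1 <- full_out$probs
  if (is.null(target_class)) {
    target <- max.col(probs1, ties.method = "first")[1]
  } else if (is.character(target_class)) {
    target <- match(target_class, SUBSET_LEVELS)
    if (is.na(target)) stop("unknown target_class: ", target_class)
  } else {
    target <- as.integer(target_class)
  }
  scale <- seq_len(m) / m
  emb_path <- list(
    Eseq = lapply(emb1$Eseq, function(v) scale %o% drop(v)),
    e_iso = scale %o% drop(emb1$e_iso),
    e_v = scale %o% drop(emb1$e_v),
    e_j = scale %o% drop(emb1$e_j))
  out <- nn_forward(params, config, emb_path, need_cache = TRUE)
  dLogits <- prob_grad_logits(out$probs, target)
  back <- nn_backward(params, config, out$cache, dLogits)
  elem <- vector("list", 28)
  names(elem) <- FEATURE_NAMES
  for (t in seq_len(config$max_len)) {
    elem[[t]] <- drop(emb1$Eseq[[t]]) * colSums(back$dEseq[[t]]) / m
  }
  elem$isotype <- drop(emb1$e_iso) * colSums(back$d_iso) / m
  elem$v_gene <- drop(emb1$e_v) * colSums(back$d_v) / m
  elem$j_gene <- drop(emb1$e_j) * colSums(back$d_j) / m
  scores <- vapply(elem, mean, numeric(1))
  f_in <- full_out$probs[1, target]
  f_base <- base_out$probs[1, target]
  structure(list(
    feature_scores = scores, elementwise = elem, m = as.integer(m),
    baseline = "zero", target_class = SUBSET_LEVELS[target],
    probs = stats::setNames(drop(probs1), SUBSET_LEVELS),
    f_input = f_in, f_baseline = f_base,
    completeness_gap = sum(unlist(elem)) - (f_in - f_base),
    sequence_length = enc$lengths[1],
    sequence_id = enc$sequence_id[1]), class = "bcr_attribution")
}

#' Attribute every record of a repertoire table
#'
#' @param model A trained `bcr_model`.
#' @param table Repertoire table.
#' @param m Interpolation steps per record.
#' @return List of [integrated_gradients()] results.
#' @export
attribute_table <- function(model, table, m = 64L) {
  lapply(seq_len(nrow(table)), function(i) {
    integrated_gradients(model, table[i, , drop = FALSE], m = m)
  })
}

#' Select high-IG features (top decile of attribution scores)
#'
#' Flags the features whose IG score falls in the top `quantile` of the
#' pooled score distribution. Pooling is per predicted-class stratum
#' (`scope = "subset"`, the default) or per instance
#' (`scope = "instance"`). Exactly `ceiling(quantile * n)` items are
#' flagged per stratum; ties at the threshold are broken deterministically
#' by canonical feature order (residue positions 1..25, then isotype, V
#' gene, J gene) and then by result index.
#'
#' @param results List of `bcr_attribution` results.
#' @param quantile Selection fraction, default 0.10.
#' @param scope Pooling scope, `"subset"` or `"instance"`.
#' @return List of logical length-28 named vectors parallel to `results`,
#'   with the per-stratum score thresholds in the `"thresholds"` attribute.
#' @export
select_high_ig <- function(results, quantile = 0.10,
                           scope = c("subset", "instance")) {
  if (length(results) == 0) stop("results must be non-empty")
  scope <- match.arg(scope)
  long <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(result = i, feature = seq_len(28),
               score = unname(results[[i]]$feature_scores),
               class = results[[i]]$target_class)
  }))
  strata <- if (scope == "subset") long$class else long$result
  flags <- lapply(results, function(r)
    stats::setNames(rep(FALSE, 28), FEATURE_NAMES))
  thresholds <- list()
  for (s in unique(strata)) {
    rows <- long[strata == s, , drop = FALSE]
    k <- ceiling(quantile * nrow(rows))
    ord <- order(-rows$score, rows$feature, rows$result)
    sel <- rows[ord[seq_len(k)], , drop = FALSE]
    if (k > 0) thresholds[[as.character(s)]] <- min(sel$score)
    for (i in seq_len(nrow(sel))) {
      flags[[sel$result[i]]][sel$feature[i]] <- TRUE
    }
  }
  attr(flags, "thresholds") <- thresholds
  flags
}

#' Composition of high-IG features by predicted subset
#'
#' For each predicted subset, the proportions of selected (high-IG)
#' features that are HCDR3 residues, isotype, V gene and J gene.
#'
#' @param results List of `bcr_attribution` results.
#' @param selections Output of [select_high_ig()].
#' @return Tibble with columns `subset`, `category`, `proportion`;
#'   proportions sum to 1 within each subset.
#' @export
composition_by_subset <- function(results, selections) {
  cat_of <- c(rep("hcdr3_residue", 25), "isotype", "v_gene", "j_gene")
  rows <- list()
  for (i in seq_along(results)) {
    sel <- which(selections[[i]])
    if (length(sel) == 0) next
    rows[[i]] <- data.frame(subset = results[[i]]$target_class,
                            category = cat_of[sel])
  }
  df <- dplyr::bind_rows(rows)
  df$category <- factor(df$category,
                        levels = c("hcdr3_residue", "isotype", "v_gene", "j_gene"))
  out <- dplyr::count(dplyr::group_by(df, .data$subset), .data$category,
                      .drop = FALSE, name = "n")
  out <- dplyr::mutate(out, proportion = .data$n / sum(.data$n))
  dplyr::ungroup(out)
}

#' Positional profile of high-IG residues at a given sequence length
#'
#' Among attributed sequences of the given HCDR3 length, the proportion
#' whose residue at each position was selected as high-IG.
#'
#' @param results List of `bcr_attribution` results.
#' @param selections Output of [select_high_ig()].
#' @param length HCDR3 length to profile.
#' @return Numeric vector of per-position proportions (length `length`),
#'   each in `[0, 1]`; empty (with a warning) if no sequence has that length.
#' @export
positional_profile <- function(results, selections, length) {
  idx <- which(vapply(results, function(r) r$sequence_length, numeric(1)) == length)
  if (base::length(idx) == 0) {
    warning("no attributed sequences of length ", length)
    return(numeric(0))
  }
  sel_mat <- do.call(rbind, lapply(idx, function(i)
    selections[[i]][seq_len(length)]))
  colMeans(sel_mat)
}

#' Paratope enrichment of high-IG residues
#'
#' Compares the proportion of residues predicted as paratope (externally
#' supplied per-residue probabilities, paratope iff probability strictly
#' greater than `threshold`) between high-IG and non-high-IG HCDR3
#' residues, with seeded bootstrap percentile confidence intervals.
#'
#' @param results List of `bcr_attribution` results.
#' @param selections Output of [select_high_ig()].
#' @param paratope_probs List parallel to `results`; element i is a numeric
#'   vector of per-residue paratope probabilities of length
#'   `results[[i]]$sequence_length`.
#' @param threshold Paratope decision threshold, default 0.488.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param boot_size Resample size per group (default: the group size).
#' @param seed Integer seed.
#' @return List with per-group `proportion`, `ci` (2.5/97.5 percentile),
#'   and `n` for groups `high_ig` and `other`.
#' @export
paratope_overlap <- function(results, selections, paratope_probs,
                             threshold = 0.488, n_boot = 1000L,
                             boot_size = NULL, seed = 1L) {
  is_para <- list(high_ig = logical(0), other = logical(0))
  for (i in seq_along(results)) {
    L <- results[[i]]$sequence_length
    p <- paratope_probs[[i]]
    if (base::length(p) != L) {
      stop("paratope probability vector ", i, " has length ", base::length(p),
           ", expected ", L)
    }
    flag <- selections[[i]][seq_len(L)]
    para <- p > threshold
    is_para$high_ig <- c(is_para$high_ig, para[flag])
    is_para$other <- c(is_para$other, para[!flag])
  }
  boot_ci <- function(x, b) {
    if (base::length(x) == 0) return(c(NA_real_, NA_real_))
    size <- boot_size %||% base::length(x)
    means <- vapply(seq_len(n_boot), function(i)
      mean(x[sample.int(base::length(x), size, replace = TRUE)]), numeric(1))
    stats::quantile(means, c(0.025, 0.975), names = FALSE)
  }
  with_seed(seed, {
    list(high_ig = list(proportion = mean(is_para$high_ig),
                        ci = boot_ci(is_para$high_ig),
                        n = base::length(is_para$high_ig)),
         other = list(proportion = mean(is_para$other),
                      ci = boot_ci(is_para$other),
                      n = base::length(is_para$other)))
  })
}
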