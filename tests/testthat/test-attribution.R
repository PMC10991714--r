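test_that("path-integral attribution is exact for linear functions at any step count", {
  # F(V) = sum(V * W) has constant gradient W, so with a zero baseline the
  # element-wise IG must equal V * W exactly for every m
  set.seed(3)
  V <- list(a = matrix(rnorm(12), 3, 4), b = rnorm(5))
  W <- list(a = matrix(rnorm(12), 3, 4), b = rnorm(5))
  grad_fun <- function(point) W
  for (m in c(1, 2, 7, 64)) {
    ig <- ig_path_integral(V, grad_fun, m = m)
    expect_equal(ig$a, V$a * W$a, tolerance = 1e-12)
    expect_equal(ig$b, V$b * W$b, tolerance = 1e-12)
  }
  expect_error(ig_path_integral(V, grad_fun, m = 0), "m must be")
})

test_that("an all-baseline instance receives zero attribution everywhere", {
  fx <- trained_fixture()
  rec <- fx$table[1, ]
  res <- integrated_gradients(fx$model, rec, m = 16)
  # padded slots equal the baseline there, so their IG is exactly 0
  L <- res$sequence_length
  pad_scores <- res$feature_scores[(L + 1):25]
  expect_equal(unname(pad_scores), rep(0, 25 - L))
  # degenerate check through the generic integrator: V = baseline -> 0
  ig <- ig_path_integral(list(x = rep(0, 4)),
                         function(p) list(x = rnorm(4)), m = 8)
  expect_equal(ig$x, rep(0, 4))
})

test_that("IG satisfies completeness with gap shrinking in the step count", {
  fx <- trained_fixture()
  rec <- fx$table[3, ]
  gaps <- vapply(c(8, 32, 128, 300), function(m) {
    r <- integrated_gradients(fx$model, rec, m = m)
    abs(r$completeness_gap) / max(abs(r$f_input - r$f_baseline), 1e-12)
  }, numeric(1))
  expect_lte(gaps[4], 1e-2)
  expect_true(all(diff(gaps) <= 0))
  # right-endpoint IG at large m agrees with an independent trapezoid-rule
  # path integral computed through the generic integrator
  model <- fx$model
  enc <- bcrsort::encode_records(rec, model$vocab)
  ns <- asNamespace("bcrsort")
  emb <- ns$embed_batch(model$params, enc, 25L)
  target <- which.max(model_forward(model, rec)$probs[1, ])
  grad_fun <- function(point) {
    out <- ns$nn_forward(model$params, model$config, point, need_cache = TRUE)
    dL <- ns$prob_grad_logits(out$probs, target)
    b <- ns$nn_backward(model$params, model$config, out$cache, dL)
    list(Eseq = b$dEseq, e_iso = b$d_iso, e_v = b$d_v, e_j = b$d_j)
  }
  # wrap nested Eseq so the generic integrator's element-wise ops apply
  flat <- function(e) c(stats::setNames(e$Eseq, paste0("t", 1:25)),
                        list(e_iso = e$e_iso, e_v = e$e_v, e_j = e$e_j))
  unflat <- function(fl) list(Eseq = unname(fl[1:25]), e_iso = fl$e_iso,
                              e_v = fl$e_v, e_j = fl$e_j)
  ig_ref <- ig_path_integral(flat(emb),
                             function(p) flat(grad_fun(unflat(p))),
                             m = 1024, scheme = "trapezoid")
  r300 <- integrated_gradients(fx$model, rec, m = 300, target_class = target)
  ref_scores <- vapply(c(paste0("t", 1:25), "e_iso", "e_v", "e_j"),
                       function(nm) mean(ig_ref[[nm]]), numeric(1))
  expect_lt(max(abs(unname(r300$feature_scores) - unname(ref_scores))), 5e-3)
})

test_that("top-decile selection flags ceil(0.1 n) features with a deterministic tie rule", {
  mk_res <- function(scores, class = "memory", len = 15L, id = "x") {
    structure(list(feature_scores = stats::setNames(scores,
                                                    bcrsort:::FEATURE_NAMES),
                   m = 8L, baseline = "zero", target_class = class,
                   sequence_length = len, sequence_id = id),
              class = "bcr_attribution")
  }
  # 100 distinct scores over 4 results x 28 features is awkward; use
  # 4 results -> 112 pooled features, top 10% = 12 flagged
  set.seed(5)
  results <- lapply(1:4, function(i) mk_res(runif(28), id = paste0("r", i)))
  sel <- select_high_ig(results)
  expect_equal(sum(unlist(sel)), ceiling(0.1 * 112))
  pooled <- unlist(lapply(results, function(r) r$feature_scores))
  cutoff <- sort(pooled, decreasing = TRUE)[ceiling(0.1 * 112)]
  expect_true(all(pooled[unlist(sel)] >= cutoff))

  # all-equal scores: the first ceil(0.1 n) in canonical feature order win
  ties <- list(mk_res(rep(1, 28)))
  sel_t <- select_high_ig(ties)
  expect_equal(unname(which(sel_t[[1]])), 1:3)  # ceil(2.8) = 3, pos01..pos03

  # quantile 1 flags everything
  sel_all <- select_high_ig(results, quantile = 1)
  expect_true(all(unlist(sel_all)))

  # per-subset pooling: strata are selected independently
  mixed <- c(lapply(1:3, function(i) mk_res(runif(28), "naive", id = paste0("n", i))),
             lapply(1:3, function(i) mk_res(runif(28) + 10, "asc", id = paste0("a", i))))
  sel_m <- select_high_ig(mixed)
  n_naive <- sum(unlist(sel_m[1:3])); n_asc <- sum(unlist(sel_m[4:6]))
  expect_equal(n_naive, ceiling(0.1 * 84))
  expect_equal(n_asc, ceiling(0.1 * 84))
})

test_that("high-IG composition sums to one per subset and reflects feature categories", {
  mk_res <- function(class) {
    structure(list(feature_scores = stats::setNames(runif(28),
                                                    bcrsort:::FEATURE_NAMES),
                   target_class = class, sequence_length = 15L,
                   sequence_id = class), class = "bcr_attribution")
  }
  set.seed(8)
  results <- lapply(c("naive", "memory", "asc"), mk_res)
  # hand-crafted selections: all residues for memory; isotype-only for naive
  sels <- list(
    stats::setNames(c(rep(FALSE, 25), TRUE, FALSE, FALSE), bcrsort:::FEATURE_NAMES),
    stats::setNames(c(rep(TRUE, 25), rep(FALSE, 3)), bcrsort:::FEATURE_NAMES),
    stats::setNames(c(rep(FALSE, 26), TRUE, TRUE), bcrsort:::FEATURE_NAMES))
  comp <- composition_by_subset(results, sels)
  sums <- tapply(comp$proportion, comp$subset, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  expect_equal(comp$proportion[comp$subset == "memory" &
                                 comp$category == "hcdr3_residue"], 1)
  expect_equal(comp$proportion[comp$subset == "naive" &
                                 comp$category == "isotype"], 1)
})

test_that("positional profile isolates the planted motif region", {
  mk_res <- function(len, id) {
    structure(list(feature_scores = stats::setNames(numeric(28),
                                                    bcrsort:::FEATURE_NAMES),
                   target_class = "memory", sequence_length = len,
                   sequence_id = id), class = "bcr_attribution")
  }
  results <- lapply(1:5, function(i) mk_res(15L, paste0("r", i)))
  sels <- lapply(1:5, function(i) {
    s <- stats::setNames(rep(FALSE, 28), bcrsort:::FEATURE_NAMES)
    s[7] <- TRUE  # every sequence selected at position 7
    s
  })
  prof <- positional_profile(results, sels, length = 15)
  expect_equal(length(prof), 15L)
  expect_equal(unname(prof), c(rep(0, 6), 1, rep(0, 8)))
  expect_true(all(prof >= 0 & prof <= 1))
  expect_warning(p0 <- positional_profile(results, sels, length = 12),
                 "no attributed sequences")
  expect_length(p0, 0L)

  # end to end: a trained model with a motif planted mid-sequence puts
  # high-IG mass on the motif window
  fx <- trained_fixture()
  idx <- utils::head(which(nchar(fx$table$hcdr3_aa) == 15 &
                             fx$table$subset == "memory"), 15)
  res <- attribute_table(fx$model, fx$table[idx, ], m = 32)
  sel <- select_high_ig(res)
  prof15 <- positional_profile(res, sel, length = 15)
  motif_mass <- mean(prof15[5:7])   # motif planted at positions 5-7
  flank_mass <- mean(prof15[c(1:4, 8:15)])
  expect_gt(motif_mass, flank_mass)
})

test_that("paratope overlap applies a strict threshold and seeded bootstrap", {
  mk_res <- function(len, id) {
    structure(list(feature_scores = stats::setNames(numeric(28),
                                                    bcrsort:::FEATURE_NAMES),
                   target_class = "memory", sequence_length = len,
                   sequence_id = id), class = "bcr_attribution")
  }
  results <- lapply(1:3, function(i) mk_res(10L, paste0("r", i)))
  sels <- lapply(1:3, function(i) {
    s <- stats::setNames(rep(FALSE, 28), bcrsort:::FEATURE_NAMES)
    s[1:3] <- TRUE
    s
  })
  all_one <- lapply(1:3, function(i) rep(1, 10))
  ov <- paratope_overlap(results, sels, all_one, seed = 2)
  expect_equal(ov$high_ig$proportion, 1)
  expect_equal(ov$other$proportion, 1)
  # exactly at the threshold is NOT a paratope (strictly greater than)
  at_thr <- lapply(1:3, function(i) rep(0.488, 10))
  ov2 <- paratope_overlap(results, sels, at_thr, seed = 2)
  expect_equal(ov2$high_ig$proportion, 0)
  # same seed -> identical CI endpoints
  set.seed(77)
  probs <- lapply(1:3, function(i) runif(10))
  a <- paratope_overlap(results, sels, probs, seed = 5, n_boot = 200)
  b <- paratope_overlap(results, sels, probs, seed = 5, n_boot = 200)
  expect_identical(a$high_ig$ci, b$high_ig$ci)
  expect_error(paratope_overlap(results, sels, lapply(1:3, function(i) rep(1, 4))),
               "length")
})
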