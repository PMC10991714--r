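mk_tab <- function(seqs, v = "IGHV1-2", j = "IGHJ4", iso = NULL, subset = NULL,
                   ids = NULL) {
  n <- length(seqs)
  bcr_repertoire(tibble::tibble(
    sequence_id = ids %||% paste0("q", seq_len(n)),
    hcdr3_aa = seqs,
    v_gene = rep_len(v, n), j_gene = rep_len(j, n),
    isotype = iso %||% rep("IgG", n),
    subset = subset %||% rep("memory", n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clonal grouping applies the strict 85% junction-identity rule", {
  base <- strrep("A", 20)
  two_mm <- paste0(strrep("A", 18), "CC")    # identity 0.90 -> merged
  # 3 mismatches at the opposite end: identity 0.85 vs base (not merged)
  # and 5 mismatches vs two_mm (no single-linkage bridge)
  three_mm <- paste0("CCC", strrep("A", 17))
  tab <- assign_clones(mk_tab(c(base, two_mm, three_mm)))
  expect_equal(tab$clone_id[1], tab$clone_id[2])
  expect_false(tab$clone_id[1] == tab$clone_id[3])
  # identical sequences, same V/J -> one clone
  same <- assign_clones(mk_tab(rep(base, 3)))
  expect_equal(length(unique(same$clone_id)), 1L)
  # same junction, different V -> never merged
  vdiff <- assign_clones(mk_tab(c(base, base), v = c("IGHV1-2", "IGHV3-23")))
  expect_equal(length(unique(vdiff$clone_id)), 2L)
})

test_that("clone assignment agrees with a brute-force single-linkage oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 100
    base <- replicate(4, paste(sample(AA_ALPHABET, 20, TRUE), collapse = ""))
    seqs <- vapply(seq_len(n), function(i) {
      b <- base[sample(4, 1)]
      k <- sample(0:4, 1)  # 3 mismatches sits exactly on the 85% boundary
      ch <- strsplit(b, "")[[1]]
      for (p in sample(20, k)) ch[p] <- sample(AA_ALPHABET, 1)
      paste(ch, collapse = "")
    }, "")
    tab <- assign_clones(mk_tab(seqs))
    # oracle: explicit all-pairs adjacency + graph components
    chm <- do.call(rbind, strsplit(seqs, ""))
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      mm <- sum(chm[i, ] != chm[j, ])
      adj[i, j] <- adj[j, i] <- (20 - mm) / 20 > 0.85 + 1e-9
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    expect_equal(as.integer(factor(tab$clone_id, levels = unique(tab$clone_id))),
                 as.integer(factor(comp, levels = unique(comp))),
                 label = paste("seed", s))
  }
})

test_that("clone assignment is invariant to input order", {
  set.seed(12)
  seqs <- replicate(40, paste(sample(AA_ALPHABET[1:4], 12, TRUE), collapse = ""))
  tab <- assign_clones(mk_tab(seqs))
  perm <- sample(40)
  tab2 <- assign_clones(mk_tab(seqs[perm], ids = paste0("q", perm)))
  m1 <- split(tab$sequence_id, tab$clone_id)
  m2 <- split(tab2$sequence_id, tab2$clone_id)
  norm <- function(m) sort(vapply(m, function(x) paste(sort(x), collapse = ","), ""))
  expect_equal(unname(norm(m1)), unname(norm(m2)))
})

test_that("lineage filtering enforces size, isotype switching and the cap", {
  big <- function(n, iso, id0) mk_tab(rep(strrep("A", 15), n), iso = iso,
                                      ids = paste0(id0, seq_len(n)))
  tab <- dplyr::bind_rows(
    big(9, c("IgG", rep("IgM", 8)), "a"),      # switched but too small
    big(10, c("IgG", rep("IgM", 9)), "b"),     # kept
    big(50, "IgM", "c"),                       # no switching -> dropped
    big(250, "IgA", "d"))                      # kept, down-sampled to 200
  tab$v_gene <- rep(c("IGHV1-1", "IGHV1-2", "IGHV1-3", "IGHV1-4"),
                    c(9, 10, 50, 250))
  tab <- bcr_repertoire(tab)
  out <- filter_lineages(assign_clones(tab), seed = 2)
  kept <- table(out$v_gene)
  expect_equal(sort(names(kept)), c("IGHV1-2", "IGHV1-4"))
  expect_equal(unname(kept[["IGHV1-2"]]), 10L)
  expect_equal(unname(kept[["IGHV1-4"]]), 200L)
  out2 <- filter_lineages(assign_clones(tab), seed = 2)
  expect_identical(out$sequence_id, out2$sequence_id)
})

test_that("the simple tree builder produces sensible NJ trees", {
  # three equidistant sequences: all terminal branches equal
  tri <- mk_tab(c("AAAAAAAAAA", "CAAAAAAAAA", "DAAAAAAAAA"))
  tr <- build_tree_simple(tri)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("q1", "q2", "q3"))
  term <- tr$edge.length[tr$edge[, 2] <= 3]
  expect_equal(unname(term), rep(term[1], 3))
  # duplicate sequences get zero-length terminal branches
  dup <- build_tree_simple(mk_tab(c("AAAAAAAAAA", "AAAAAAAAAA", "CCCAAAAAAA")))
  d <- stats::cophenetic(dup)
  expect_equal(d["q1", "q2"], 0)
  # tree distances reproduce the (additive) Hamming distances
  seqs <- c("AAAAAAAAAA", "CAAAAAAAAA", "CCCAAAAAAA", "CCCCCAAAAA")
  tr2 <- build_tree_simple(mk_tab(seqs))
  chm <- do.call(rbind, strsplit(seqs, ""))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(stats::cophenetic(tr2)[paste0("q", i), paste0("q", j)],
                 sum(chm[i, ] != chm[j, ]), tolerance = 1e-9)
  }
  expect_error(build_tree_simple(mk_tab("AAAAAAAAAA")), "at least 2")
  # germline rooting places the germline as an outgroup tip
  tg <- build_tree_simple(tri, germline = "AAAAAAAAAA")
  expect_true("Germline" %in% tg$tip.label)
})

test_that("differentiation-order violations are detected from divergence order", {
  # ladder: naive diverges first, then memory, then asc -> no violation
  ladder <- ape::read.tree(text = "(n1:1,(m1:1,(a1:1,a2:2):1):1);")
  subsets <- c(n1 = "naive", m1 = "memory", a1 = "asc", a2 = "asc")
  expect_false(needs_reroot(ladder, subsets))
  # an ASC diverging at the root before a naive leaf -> violation
  bad <- ape::read.tree(text = "(a1:1,(m1:1,(n1:1,n2:2):1):1);")
  subsets2 <- c(a1 = "asc", m1 = "memory", n1 = "naive", n2 = "naive")
  expect_true(needs_reroot(bad, subsets2))
  # trees without naive leaves can never violate
  allm <- ape::read.tree(text = "(m1:1,(m2:1,m3:1):1);")
  expect_false(needs_reroot(allm, c(m1 = "memory", m2 = "memory", m3 = "memory")))
  expect_error(needs_reroot(ladder, subsets[1:2]), "subset label")
})

test_that("new-root selection prefers least-mutated naive cells from the earliest timepoint", {
  bad <- ape::read.tree(text = "(a1:1,(m1:1,(n1:1,n2:2):1):1);")
  subsets <- c(a1 = "asc", m1 = "memory", n1 = "naive", n2 = "naive")
  shm <- c(a1 = 9, m1 = 6, n1 = 5, n2 = 2)
  rep1 <- select_new_root(bad, subsets, shm, seed = 1)
  expect_true(rep1$violation)
  expect_equal(rep1$chosen_root, "n2")   # least mutated naive
  expect_false(rep1$tie_broken)
  # ties broken reproducibly at a fixed seed
  shm_tie <- c(a1 = 9, m1 = 6, n1 = 2, n2 = 2)
  r_a <- select_new_root(bad, subsets, shm_tie, seed = 7)
  r_b <- select_new_root(bad, subsets, shm_tie, seed = 7)
  expect_true(r_a$tie_broken)
  expect_identical(r_a$chosen_root, r_b$chosen_root)
  # earliest-timepoint restriction overrides a later, less-mutated naive
  tp <- c(a1 = 1, m1 = 1, n1 = 1, n2 = 2)
  shm_tp <- c(a1 = 9, m1 = 6, n1 = 3, n2 = 0)
  r_tp <- select_new_root(bad, subsets, shm_tp, timepoints = tp, seed = 1)
  expect_equal(r_tp$chosen_root, "n1")
  # no naive leaf -> rerooting impossible
  expect_error(select_new_root(bad, c(a1 = "asc", m1 = "memory",
                                      n1 = "memory", n2 = "asc"), shm),
               "no naive leaf")
})

test_that("rerooting preserves leaves and the unrooted split set, drops the germline", {
  sim <- simulate_lineage(n_leaves = 12, seed = 33)
  subsets <- stats::setNames(sim$members$subset, sim$members$sequence_id)
  bad <- misroot(sim$tree, subsets, seed = 2)
  target <- sim$members$sequence_id[which.min(sim$members$shm_count)]
  re <- reroot_tree(bad, target)
  expect_equal(sort(re$tip.label), sort(bad$tip.label))
  expect_identical(bcrsort:::tree_splits(bad), bcrsort:::tree_splits(re))
  # idempotent
  re2 <- reroot_tree(re, target)
  expect_identical(bcrsort:::tree_splits(re), bcrsort:::tree_splits(re2))
  expect_equal(sort(re2$tip.label), sort(re$tip.label))
  # germline tip is removed before rerooting
  tg <- build_tree_simple(sim$members, germline = sim$germline)
  reg <- reroot_tree(tg, target)
  expect_false("Germline" %in% reg$tip.label)
  expect_error(reroot_tree(bad, "nonexistent"), "not a leaf")
})

test_that("evolution order ranks leaves by divergence and matches a path-length oracle", {
  ladder <- ape::read.tree(text = "(n1:1,(m1:1.5,(a1:2,a2:3):1):1);")
  ord <- evolution_order(ladder)
  expect_equal(ord$sequence_id, c("n1", "m1", "a1", "a2"))
  expect_equal(ord$rank, 1:4)
  # brute-force root-to-tip path lengths by walking edges
  brute_depth <- function(tree, tip) {
    node <- match(tip, tree$tip.label)
    depth <- 0
    repeat {
      row <- which(tree$edge[, 2] == node)
      if (length(row) == 0) break
      depth <- depth + tree$edge.length[row]
      node <- tree$edge[row, 1]
    }
    depth
  }
  sim <- simulate_lineage(n_leaves = 10, seed = 44)
  ord2 <- evolution_order(sim$tree)
  for (i in seq_len(nrow(ord2))) {
    expect_equal(ord2$depth[i], brute_depth(sim$tree, ord2$sequence_id[i]),
                 tolerance = 1e-9)
  }
  # ultrametric ties fall back to canonical leaf order
  star <- ape::read.tree(text = "(c:1,a:1,b:1);")
  expect_equal(evolution_order(star)$sequence_id, c("a", "b", "c"))
})

test_that("order rank correlation behaves as Spearman on shared leaves", {
  ladder <- ape::read.tree(text = "(n1:1,(m1:1.5,(a1:2,a2:3):1):1);")
  expect_equal(order_rank_correlation(ladder, ladder), 1)
  rev_rank <- stats::setNames(4:1, c("n1", "m1", "a1", "a2"))
  expect_equal(order_rank_correlation(ladder, rev_rank), -1)
  expect_error(order_rank_correlation(ladder,
                                      stats::setNames(1:2, c("n1", "m1"))),
               "at least 3")
})

test_that("thirds of the divergence range partition the leaves as expected", {
  # 9 leaves at depths 1..9: three per third
  nwk <- paste0("(", paste(sprintf("t%d:%d", 1:9, 1:9), collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  ann <- stats::setNames(rep(c("naive", "memory", "asc"), each = 3),
                         paste0("t", 1:9))
  tab <- thirds_distribution(tree, ann)
  expect_equal(unname(rowSums(tab)), c(3, 3, 3))
  # single-category tree fills all thirds with that category
  one <- thirds_distribution(tree, stats::setNames(rep("memory", 9),
                                                   paste0("t", 1:9)))
  expect_equal(colnames(one), "memory")
  expect_equal(unname(rowSums(one)), c(3, 3, 3))
  # rerooting a misrooted lineage moves naive cells into the earliest third
  sim <- simulate_lineage(n_leaves = 20, seed = 55)
  subsets <- stats::setNames(sim$members$subset, sim$members$sequence_id)
  shm <- stats::setNames(sim$members$shm_count, sim$members$sequence_id)
  bad <- misroot(sim$tree, subsets, seed = 3)
  rep_ <- select_new_root(bad, subsets, shm, seed = 3)
  re <- reroot_tree(bad, rep_$chosen_root)
  th_bad <- thirds_distribution(bad, subsets)
  th_re <- thirds_distribution(re, subsets)
  naive_share <- function(m) {
    if (!"naive" %in% colnames(m)) return(0)
    m["early", "naive"] / max(sum(m["early", ]), 1)
  }
  expect_gte(naive_share(th_re), naive_share(th_bad))
})

test_that("persistent clones require presence at every timepoint and a switched isotype", {
  t1 <- mk_tab(c("CARDYWGQGT", "CAKEGYSSGW", "CCCDDDEEEE"),
               iso = c("IgG", "IgM", "IgM"), ids = paste0("t1_", 1:3))
  t2 <- mk_tab(c("CARDYWGQGT", "CAKEGYSSGW"),
               iso = c("IgA", "IgM"), ids = paste0("t2_", 1:2))
  t3 <- mk_tab(c("CARDYWGQGT", "CAKEGYSSGW", "CARDYWGQGT"),
               iso = c("IgM", "IgM", "IgM"), ids = paste0("t3_", 1:3))
  out <- persistent_clones(list(pre = t1, mid = t2, relapse = t3))
  # CARDY... is in all three timepoints with IgG/IgA members -> persistent
  # CAKEG... is in all three but always IgM -> excluded
  # CCCDD... is only in t1 -> not persistent
  expect_equal(out$hcdr3_aa, "CARDYWGQGT")
  expect_error(persistent_clones(list(t1)), "at least 2")
})
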