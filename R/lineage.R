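# Clonal grouping, lineage filtering, tree building, cell-subset-aware
# rerooting and its evaluation, and persistent-clone detection.
# Trees are ape "phylo" objects with tip labels equal to sequence_ids.

# identity > threshold, tolerant of the float representation of e.g. 0.85
identity_links <- function(mm, L, threshold) {
  (L - mm) / L > threshold + 1e-9
}

#' Assign sequences to clones by junction similarity
#'
#' Sequences sharing identical V and J genes and junction length are
#' single-linkage clustered: two sequences are linked when their junction
#' (HCDR3) Hamming identity strictly exceeds `similarity_threshold`; clones
#' are the connected components. Sequences of unequal junction length never
#' merge.
#'
#' @param table Repertoire table.
#' @param similarity_threshold Identity threshold, default 0.85.
#' @return The table with a `clone_id` column added (clone ids are
#'   `"clone_"` + dense integer, assigned in first-appearance order).
#' @export
assign_clones <- function(table, similarity_threshold = 0.85) {
  n <- nrow(table)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  bucket <- paste(table$v_gene, table$j_gene, nchar(table$hcdr3_aa), sep = "\r")
  for (b in unique(bucket)) {
    idx <- which(bucket == b)
    if (length(idx) < 2) next
    L <- nchar(table$hcdr3_aa[idx[1]])
    chm <- char_matrix(table$hcdr3_aa[idx])
    for (i in seq_len(length(idx) - 1)) {
      rest <- (i + 1):length(idx)
      mm <- rowSums(chm[rest, , drop = FALSE] !=
                      matrix(chm[i, ], length(rest), L, byrow = TRUE))
      for (j in rest[identity_links(mm, L, similarity_threshold)]) {
        union_(idx[i], idx[j])
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  table$clone_id <- paste0("clone_", match(roots, unique(roots)))
  table
}

#' Filter clones to actively maturing lineages and down-sample large ones
#'
#' Retains clones with at least `min_size` members that show isotype
#' switching (at least one member with a switched isotype: IgG, IgA or
#' IgE). Clones with more than `downsample_cap` members are down-sampled
#' (seeded, uniform without replacement) to `downsample_cap`.
#'
#' @param table Repertoire table with a `clone_id` column
#'   (see [assign_clones()]).
#' @param min_size Minimum clone size, default 10.
#' @param downsample_cap Maximum clone size before down-sampling,
#'   default 200.
#' @param seed Integer seed.
#' @return Filtered (and possibly down-sampled) repertoire table.
#' @export
filter_lineages <- function(table, min_size = 10L, downsample_cap = 200L,
                            seed = 1L) {
  if (!"clone_id" %in% names(table)) stop("run assign_clones first")
  keep_rows <- integer(0)
  clone_ids <- unique(table$clone_id)
  for (ci in seq_along(clone_ids)) {
    rows <- which(table$clone_id == clone_ids[ci])
    if (length(rows) < min_size) next
    if (!any(table$isotype[rows] %in% SWITCHED_ISOTYPES)) next
    if (length(rows) > downsample_cap) {
      rows <- with_seed(seed + ci, sort(sample(rows, downsample_cap)))
    }
    keep_rows <- c(keep_rows, rows)
  }
  table[sort(keep_rows), , drop = FALSE]
}

#' Build a simple lineage tree for one clone
#'
#' Neighbor-joining tree on pairwise Hamming distances between member
#' sequences (nucleotide junctions when every member has one, amino-acid
#' junctions otherwise), midpoint-rooted, or rooted on a supplied germline
#' sequence added as an extra leaf named `"Germline"`. A convenience
#' stand-in for maximum-likelihood lineage inference; rerooting operates on
#' any supplied rooted tree.
#'
#' @param clone Repertoire table rows of a single clone (>= 2 members).
#' @param germline Optional germline junction sequence (same length).
#' @return An ape `phylo` tree with tip labels = `sequence_id`
#'   (plus `"Germline"` when supplied).
#' @export
build_tree_simple <- function(clone, germline = NULL) {
  if (nrow(clone) < 2) stop("need at least 2 members to build a tree")
  use_nt <- "hcdr3_nt" %in% names(clone) && !anyNA(clone$hcdr3_nt) &&
    length(unique(nchar(clone$hcdr3_nt))) == 1
  seqs <- if (use_nt) clone$hcdr3_nt else clone$hcdr3_aa
  labels <- clone$sequence_id
  if (!is.null(germline)) {
    seqs <- c(seqs, germline)
    labels <- c(labels, "Germline")
  }
  chm <- char_matrix(seqs)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- sum(chm[i, ] != chm[j, ])
    }
  }
  if (n == 2) {
    tree <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", labels[1],
                                          D[1, 2] / 2, labels[2], D[1, 2] / 2))
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (!is.null(germline)) {
    tree <- ape::root(tree, outgroup = "Germline", resolve.root = TRUE)
  } else {
    tree <- phangorn::midpoint(tree)
  }
  tree
}

# Root-to-tip path lengths (divergence depths) for every tip, named.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Does a lineage tree violate the order of B-cell differentiation?
#'
#' Checks whether any antigen-experienced leaf (memory or ASC) precedes an
#' antigen-unexperienced naive leaf along the tree: an experienced leaf
#' precedes a naive leaf when its divergence point (the depth of the node
#' where its terminal branch attaches) is strictly shallower than the
#' naive leaf's own root-to-leaf depth. Such a tree implies an
#' evolutionary scenario contradicting naive-to-experienced
#' differentiation and is a candidate for rerooting.
#'
#' @param tree Rooted `phylo` tree.
#' @param subsets Named character vector (names = tip labels) of subset
#'   labels for every leaf.
#' @return TRUE when a violation is present.
#' @export
needs_reroot <- function(tree, subsets) {
  tips <- tree$tip.label
  if (!all(tips %in% names(subsets)) || anyNA(subsets[tips])) {
    stop("every leaf must carry a subset label")
  }
  subsets <- subsets[tips]
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tips)
  parent_depth <- stats::setNames(
    depths[tree$edge[match(seq_len(ntip), tree$edge[, 2]), 1]], tips)
  d <- stats::setNames(depths[seq_len(ntip)], tips)
  naive <- tips[subsets == "naive"]
  exper <- tips[subsets %in% c("memory", "asc")]
  if (length(naive) == 0 || length(exper) == 0) return(FALSE)
  min(parent_depth[exper]) < max(d[naive])
}

#' Select the new root for a violating lineage tree
#'
#' Candidates are the naive leaves, restricted to those from the earliest
#' timepoint represented in the lineage when timepoints are given (falling
#' back to the earliest timepoint that has a naive member). The winner is
#' the least-mutated candidate by SHM count; ties are broken by seeded
#' uniform sampling.
#'
#' @param tree Rooted `phylo` tree.
#' @param subsets Named character vector of per-leaf subset labels.
#' @param shm_counts Named numeric vector of per-leaf SHM counts.
#' @param timepoints Optional named vector of per-leaf timepoint order
#'   (smaller = earlier; character timepoints are ranked by factor order).
#' @param seed Integer seed for tie-breaking.
#' @return A `bcr_reroot_report` list: `violation`, `chosen_root`,
#'   `candidates` (tibble of leaf, shm, timepoint), `tie_broken`, `seed`.
#' @export
select_new_root <- function(tree, subsets, shm_counts, timepoints = NULL,
                            seed = 1L) {
  violation <- needs_reroot(tree, subsets)
  tips <- tree$tip.label
  naive <- tips[subsets[tips] == "naive"]
  if (length(naive) == 0) {
    stop("no naive leaf in the lineage; rerooting impossible")
  }
  cand <- naive
  tp_used <- NA
  if (!is.null(timepoints)) {
    tp <- timepoints[tips]
    tp_rank <- if (is.numeric(tp)) tp else as.integer(factor(tp, levels = unique(sort(tp))))
    names(tp_rank) <- tips
    for (t in sort(unique(tp_rank))) {
      at_t <- intersect(naive, tips[tp_rank == t])
      if (length(at_t) > 0) { cand <- at_t; tp_used <- t; break }
    }
  }
  shm <- shm_counts[cand]
  if (anyNA(shm)) stop("shm_counts missing for candidate leaves")
  best <- cand[shm == min(shm)]
  tie <- length(best) > 1
  chosen <- if (tie) with_seed(seed, sample(best, 1)) else best
  structure(list(violation = violation, chosen_root = chosen,
                 candidates = tibble::tibble(leaf = cand, shm = unname(shm)),
                 earliest_timepoint = tp_used,
                 tie_broken = tie, seed = seed),
            class = "bcr_reroot_report")
}

#' Reroot a lineage tree on a chosen leaf
#'
#' Removes the virtual germline leaf (tip named `germline_label`) if
#' present, then re-roots the tree on `new_root`. The unrooted topology
#' (split set) and the remaining leaf set are preserved; only
#' ancestor-descendant orientation changes.
#'
#' @param tree Rooted `phylo` tree.
#' @param new_root Tip label to root on.
#' @param germline_label Name of the virtual germline tip (default
#'   `"Germline"`); ignored when absent.
#' @return Rerooted `phylo` tree.
#' @export
reroot_tree <- function(tree, new_root, germline_label = "Germline") {
  if (germline_label %in% tree$tip.label && new_root != germline_label) {
    tree <- ape::drop.tip(tree, germline_label)
  }
  if (!new_root %in% tree$tip.label) {
    stop("new_root '", new_root, "' is not a leaf of the tree")
  }
  ape::root(tree, outgroup = new_root, resolve.root = TRUE)
}

#' Rank leaves by evolutionary (divergence) order
#'
#' Leaves are ranked by root-to-leaf path length; ties are broken by
#' canonical (alphabetical) leaf id.
#'
#' @param tree Rooted `phylo` tree.
#' @return Tibble: `sequence_id`, `depth`, `rank` (1 = earliest).
#' @export
evolution_order <- function(tree) {
  d <- tip_depths(tree)
  ord <- order(d, names(d))
  tibble::tibble(sequence_id = names(d)[ord],
                 depth = unname(d[ord]),
                 rank = seq_along(d))
}

#' Rank correlation of evolutionary order between two trees
#'
#' Spearman correlation between leaf divergence depths over the leaves
#' shared by the two trees (or between a tree and a reference ranking).
#'
#' @param tree_a,tree_b Rooted `phylo` trees, or named numeric vectors of
#'   leaf order/depth.
#' @return Spearman's rho.
#' @export
order_rank_correlation <- function(tree_a, tree_b) {
  depth_of <- function(x) {
    if (inherits(x, "phylo")) tip_depths(x) else x
  }
  da <- depth_of(tree_a); db <- depth_of(tree_b)
  shared <- intersect(names(da), names(db))
  if (length(shared) < 3) stop("need at least 3 shared leaves")
  stats::cor(da[shared], db[shared], method = "spearman")
}

#' Annotation counts over the early/middle/late thirds of a lineage
#'
#' Bins leaves into thirds of the root-to-leaf divergence range
#' (`[0, max depth]` split into three equal intervals) and counts an
#' annotation (subset or isotype) within each third.
#'
#' @param tree Rooted `phylo` tree.
#' @param annotations Named vector (names = tip labels) of categories.
#' @return Matrix: 3 rows (early/middle/late) x categories.
#' @export
thirds_distribution <- function(tree, annotations) {
  d <- tip_depths(tree)
  if (!all(names(d) %in% names(annotations))) {
    stop("every leaf must carry an annotation")
  }
  breaks <- seq(0, max(d), length.out = 4)
  if (max(d) == 0) breaks <- c(0, 1, 2, 3)  # degenerate star: all early
  third <- cut(d, breaks = breaks, include.lowest = TRUE,
               labels = c("early", "middle", "late"))
  tab <- table(third = third, category = annotations[names(d)])
  unclass(tab)
}

#' Persistent clones across timepoints
#'
#' A clone key (V gene, J gene, HCDR3 amino-acid sequence) is persistent
#' when present in every supplied timepoint table. Keys whose pooled
#' members are composed solely of IgM or IgD records are excluded, to
#' focus on antigen-experienced responses.
#'
#' @param tables Named list of repertoire tables, one per timepoint
#'   (>= 2 timepoints).
#' @return Tibble of persistent keys: `v_gene`, `j_gene`, `hcdr3_aa`.
#' @export
persistent_clones <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 timepoints")
  key_of <- function(tb) paste(tb$v_gene, tb$j_gene, tb$hcdr3_aa, sep = "\r")
  keys <- Reduce(intersect, lapply(tables, key_of))
  if (length(keys) == 0) {
    return(tibble::tibble(v_gene = character(), j_gene = character(),
                          hcdr3_aa = character()))
  }
  pooled <- dplyr::bind_rows(tables)
  pk <- key_of(pooled)
  has_switched <- vapply(keys, function(k) {
    any(!(pooled$isotype[pk == k] %in% c("IgM", "IgD")))
  }, logical(1))
  parts <- strsplit(keys[has_switched], "\r", fixed = TRUE)
  tibble::tibble(v_gene = vapply(parts, `[`, "", 1),
                 j_gene = vapply(parts, `[`, "", 2),
                 hcdr3_aa = vapply(parts, `[`, "", 3))
}

# Non-trivial splits (bipartitions) of an unrooted tree as a canonical
# character set; used to verify that rerooting preserves topology.
tree_splits <- function(tree, exclude = "Germline") {
  if (exclude %in% tree$tip.label && length(tree$tip.label) > 3) {
    tree <- ape::drop.tip(tree, exclude)
  }
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all_tips <- sort(labs)
  canon <- vapply(parts, function(p) {
    side <- sort(labs[p])
    other <- setdiff(all_tips, side)
    if (length(side) <= 1 || length(other) <= 1) return(NA_character_)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }, character(1))
  sort(unique(canon[!is.na(canon)]))
}
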