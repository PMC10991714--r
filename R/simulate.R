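# Synthetic-repertoire and synthetic-lineage generator. Emulates the
# statistical structure the classifier exploits — subset-dependent SHM
# load, subset-conditional isotype usage, V/J usage, optional subset-
# discriminative sequence motifs — and clonal lineages with a known
# evolution order, so every analysis module is testable without external
# data downloads.

#' Generative parameters for the synthetic repertoire
#'
#' Defaults describe a three-subset repertoire at equal priors with
#' naive cells carrying near-germline sequences (low Poisson SHM mean,
#' IgM/IgD isotypes) and antigen-experienced cells carrying progressively
#' more substitutions and class-switched isotypes. Lengths are drawn from
#' a distribution over 8–25 peaked at 15, the dominant HCDR3 length in
#' human repertoires.
#'
#' @param n_records Number of records to simulate.
#' @param subset_priors Named length-3 probability vector (naive, memory, asc).
#' @param shm_means Named length-3 Poisson means of amino-acid
#'   substitution counts per subset.
#' @param isotype_probs Named list: per-subset named probability vectors
#'   over the 5 isotypes.
#' @param v_genes,j_genes Toy gene name vectors.
#' @param v_usage,j_usage Usage probability vectors (default uniform).
#' @param motifs Optional named list: per-subset
#'   `list(motif = <string>, position = <start>, prob = <insertion prob>)`,
#'   planting a subset-discriminative motif.
#' @param length_probs Named probability vector over lengths 8..25.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    n_records = 2000L,
    subset_priors = c(naive = 1 / 3, memory = 1 / 3, asc = 1 / 3),
    shm_means = c(naive = 0.3, memory = 4, asc = 6),
    isotype_probs = list(
      naive = c(IgM = 0.85, IgD = 0.15, IgG = 0, IgA = 0, IgE = 0),
      memory = c(IgM = 0.20, IgD = 0.02, IgG = 0.50, IgA = 0.25, IgE = 0.03),
      asc = c(IgM = 0.08, IgD = 0.01, IgG = 0.55, IgA = 0.34, IgE = 0.02)),
    v_genes = sprintf("IGHV%d-%d", rep(1:5, each = 2), rep(c(2, 23), 5)),
    j_genes = sprintf("IGHJ%d", c(1, 3, 4, 6)),
    v_usage = NULL, j_usage = NULL,
    motifs = NULL,
    length_probs = NULL,
    seed = 1L) {
  stopifnot(abs(sum(subset_priors) - 1) < 1e-9, all(shm_means >= 0))
  for (p in isotype_probs) stopifnot(abs(sum(p) - 1) < 1e-9)
  if (is.null(length_probs)) {
    lens <- 8:25
    w <- stats::dnorm(lens, mean = 15, sd = 3)
    length_probs <- stats::setNames(w / sum(w), lens)
  }
  stopifnot(abs(sum(length_probs) - 1) < 1e-9)
  if (!is.null(motifs)) {
    min_len <- min(as.integer(names(length_probs)[length_probs > 0]))
    for (m in motifs) {
      if (nchar(m$motif) > min_len) {
        stop("motif longer than the minimum sequence length")
      }
    }
  }
  structure(list(n_records = as.integer(n_records),
                 subset_priors = subset_priors[SUBSET_LEVELS],
                 shm_means = shm_means[SUBSET_LEVELS],
                 isotype_probs = isotype_probs,
                 v_genes = v_genes, j_genes = j_genes,
                 v_usage = v_usage %||% rep(1 / length(v_genes), length(v_genes)),
                 j_usage = j_usage %||% rep(1 / length(j_genes), length(j_genes)),
                 motifs = motifs, length_probs = length_probs,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_aa_seq <- function(L) {
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

apply_substitutions <- function(seq, k) {
  L <- nchar(seq)
  k <- min(k, L)
  if (k == 0) return(seq)
  pos <- sample.int(L, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(AA_ALPHABET, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate a labeled repertoire
#'
#' Per record: draw a subset from the priors, a germline HCDR3 (uniform
#' residues at a drawn length), apply a Poisson(subset mean) number of
#' random single-residue substitutions (recorded as the true `shm_count`),
#' optionally plant the subset's discriminative motif, and draw isotype
#' and V/J genes from the subset-conditional tables. Deterministic given
#' the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A labeled `bcr_repertoire` with true `subset` and `shm_count`.
#' @export
simulate_repertoire <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_records
    subset <- sample(SUBSET_LEVELS, n, replace = TRUE, prob = spec$subset_priors)
    lens <- as.integer(sample(names(spec$length_probs), n, replace = TRUE,
                              prob = spec$length_probs))
    hcdr3 <- character(n); shm <- integer(n)
    iso <- character(n); vg <- character(n); jg <- character(n)
    for (i in seq_len(n)) {
      seq <- random_aa_seq(lens[i])
      k <- stats::rpois(1, spec$shm_means[[subset[i]]])
      shm[i] <- min(k, lens[i])
      seq <- apply_substitutions(seq, k)
      mo <- spec$motifs[[subset[i]]]
      if (!is.null(mo) && stats::runif(1) < mo$prob) {
        start <- min(max(1L, mo$position), lens[i] - nchar(mo$motif) + 1L)
        substr(seq, start, start + nchar(mo$motif) - 1L) <- mo$motif
      }
      hcdr3[i] <- seq
      iso[i] <- sample(names(spec$isotype_probs[[subset[i]]]), 1,
                       prob = spec$isotype_probs[[subset[i]]])
      vg[i] <- sample(spec$v_genes, 1, prob = spec$v_usage)
      jg[i] <- sample(spec$j_genes, 1, prob = spec$j_usage)
    }
    bcr_repertoire(tibble::tibble(
      sequence_id = sprintf("sim%06d", seq_len(n)),
      hcdr3_aa = hcdr3, v_gene = vg, j_gene = jg, isotype = iso,
      subset = subset, shm_count = shm),
      provenance = list(list(source = "simulate_repertoire",
                             seed = spec$seed, n = n)))
  })
}

#' Simulate a clonal lineage with known evolution order
#'
#' Grows a random bifurcating tree from a naive, IgM, unmutated germline
#' junction. Substitutions accumulate along branches (Poisson per branch),
#' so divergence depth tracks mutation load; subsets progress
#' naive → memory → asc and isotypes IgM → switched monotonically along
#' every root-to-leaf path. The true evolution order is the birth order of
#' the leaves. Leaves are binned into three consecutive timepoints by
#' birth order. The member sequences are guaranteed to form a single clone
#' at the clonal-identity threshold, otherwise an error is raised.
#'
#' @param n_leaves Number of leaves (>= 3).
#' @param junction_length Junction length (default 24).
#' @param branch_mut_mean Poisson mean of substitutions per branch.
#' @param advance_prob Per-branch probability of advancing one subset
#'   stage (naive to memory, memory to asc).
#' @param switch_prob Per-branch probability that a non-naive, still-IgM
#'   child class-switches (to IgG or IgA).
#' @param v_gene,j_gene Gene names shared by the clone.
#' @param seed Integer seed.
#' @param similarity_threshold Clonal identity threshold used for the
#'   single-clone guarantee check.
#' @return List: `members` (labeled `bcr_repertoire` with `shm_count` and
#'   `timepoint_order`), `tree` (true rooted `phylo`, root = germline),
#'   `true_order` (named rank vector, 1 = earliest-born leaf),
#'   `germline` (junction string).
#' @export
simulate_lineage <- function(n_leaves = 20L, junction_length = 24L,
                             branch_mut_mean = 0.2, advance_prob = 0.35,
                             switch_prob = 0.7, v_gene = "IGHV3-23",
                             j_gene = "IGHJ4", seed = 1L,
                             similarity_threshold = 0.85) {
  if (n_leaves < 3) stop("n_leaves must be >= 3")
  with_seed(seed, {
    germline <- random_aa_seq(junction_length)
    # node store; node 1 is the germline root
    seqs <- germline; subset <- "naive"; isotype <- "IgM"
    shm <- 0L; parent <- 0L; elen <- 0; birth <- 0L
    children <- list(integer(0))
    new_child <- function(par) {
      k <- stats::rpois(1, branch_mut_mean)
      s <- apply_substitutions(seqs[par], k)
      sub <- subset[par]
      if (sub != "asc" && stats::runif(1) < advance_prob) {
        sub <- SUBSET_LEVELS[match(sub, SUBSET_LEVELS) + 1]
      }
      iso <- isotype[par]
      if (sub != "naive" && iso %in% c("IgM", "IgD") &&
          stats::runif(1) < switch_prob) {
        iso <- sample(c("IgG", "IgA"), 1)
      }
      seqs <<- c(seqs, s); subset <<- c(subset, sub); isotype <<- c(isotype, iso)
      shm <<- c(shm, shm[par] + k); parent <<- c(parent, par)
      elen <<- c(elen, k + 0.5)  # +0.5 keeps depths strictly increasing
      birth <<- c(birth, max(birth) + 1L)
      children[[par]] <<- c(children[[par]], length(seqs))
      children[[length(seqs)]] <<- integer(0)
      length(seqs)
    }
    leaves <- c(new_child(1L), new_child(1L))
    while (length(leaves) < n_leaves) {
      pick <- sample(seq_along(leaves), 1)
      node <- leaves[pick]
      leaves <- leaves[-pick]
      leaves <- c(leaves, new_child(node), new_child(node))
    }
    # guards: the evaluation of rerooting needs both a naive and an
    # experienced leaf; relabel extremes in the rare runs lacking one
    if (!any(subset[leaves] == "naive")) {
      i <- leaves[which.min(shm[leaves])]
      subset[i] <- "naive"; isotype[i] <- "IgM"
    }
    if (!any(subset[leaves] %in% c("memory", "asc"))) {
      i <- leaves[which.max(shm[leaves])]
      subset[i] <- "memory"
    }
    leaf_label <- stats::setNames(
      sprintf("L%03d", rank(birth[leaves], ties.method = "first")), leaves)
    to_newick <- function(node) {
      if (length(children[[node]]) == 0) {
        sprintf("%s:%g", leaf_label[[as.character(node)]], elen[node])
      } else {
        sprintf("(%s):%g",
                paste(vapply(children[[node]], to_newick, character(1)),
                      collapse = ","), elen[node])
      }
    }
    tree <- ape::read.tree(text = paste0(to_newick(1L), ";"))
    ord <- order(birth[leaves])
    true_order <- stats::setNames(seq_along(leaves),
                                  leaf_label[as.character(leaves[ord])])
    members <- bcr_repertoire(tibble::tibble(
      sequence_id = unname(leaf_label[as.character(leaves)]),
      hcdr3_aa = seqs[leaves], v_gene = v_gene, j_gene = j_gene,
      isotype = isotype[leaves], subset = subset[leaves],
      shm_count = as.integer(shm[leaves]),
      timepoint_order = as.integer(cut(rank(birth[leaves],
                                            ties.method = "first"),
                                       breaks = 3, labels = FALSE))))
    cl <- assign_clones(members, similarity_threshold)
    if (length(unique(cl$clone_id)) != 1) {
      stop("simulated members do not form a single clone at identity > ",
           similarity_threshold,
           "; lower branch_mut_mean or increase junction_length")
    }
    list(members = members, tree = tree, true_order = true_order,
         germline = germline)
  })
}

#' Misroot a lineage tree on an antigen-experienced leaf
#'
#' Re-roots the tree on a seeded random memory/ASC leaf, producing a tree
#' that violates the order of B-cell differentiation (an experienced cell
#' preceding naive cells) — the "before" condition for evaluating
#' subset-aware rerooting.
#'
#' @param tree Rooted `phylo` tree.
#' @param subsets Named per-leaf subset labels.
#' @param seed Integer seed.
#' @return Misrooted `phylo` tree (leaf set preserved).
#' @export
misroot <- function(tree, subsets, seed = 1L) {
  exper <- tree$tip.label[subsets[tree$tip.label] %in% c("memory", "asc")]
  if (length(exper) == 0) stop("no antigen-experienced leaf to misroot on")
  pick <- with_seed(seed, sample(exper, 1))
  ape::root(tree, outgroup = pick, resolve.root = TRUE)
}
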