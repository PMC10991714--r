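---
title: "Classifying B-cell subsets from BCR sequence: model, attribution and lineage rerooting"
author: "bcrsort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying B-cell subsets from BCR sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrsort)
```

## The problem

As B cells respond to antigen they differentiate from naive cells into
memory B cells and antibody-secreting cells (ASCs), and their receptors
(BCRs) change with them: somatic hypermutation (SHM) accumulates point
substitutions in the variable region, and class switching replaces IgM/IgD
with IgG, IgA or IgE. These processes leave a statistical signature in the
sequence itself. `bcrsort` exploits that signature to predict, for a single
heavy-chain rearrangement, the subset of the cell that carried it — using
only the HCDR3 amino-acid sequence, the IGHV and IGHJ gene calls and the
isotype. Around the classifier the package provides the downstream analyses
that make such a model useful: feature attribution, in-silico saturation
mutagenesis, transfer learning to new cohorts, and cell-subset-aware
rerooting of clonal lineage trees.

## The classifier

The model consumes four inputs per record. The HCDR3 is tokenized over the
20 amino acids, right-padded with a PAD token to 25 positions (sequences of
length 8–25 are accepted; shorter and longer HCDR3s are filtered out
beforehand with `filter_hcdr3_length()`). The sequence branch is a
learnable residue embedding, a 2-layer bidirectional LSTM, and three
1-dimensional convolutions with ReLU activations, followed by global max
pooling over positions — pooling is length-invariant and suits motif
detection, which is what the convolutions learn. Isotype, V gene and J gene
each pass through their own categorical embedding (V and J have a trailing
out-of-vocabulary index for genes unseen at training time). The pooled
sequence vector and the three categorical embeddings are concatenated and
fed to a 3-layer MLP ending in a softmax over (naive, memory, asc) — this
class order is fixed everywhere, including confusion matrices.

During pre-training an auxiliary task regularizes the sequence branch: one
residue per HCDR3 is replaced by a MASK token and a 20-way head must
recover it from the fused feature vector. The total loss is

    L = CE(subset) + 0.05 * CE(masked residue)

with both cross-entropies averaged over the batch. Training uses Adam at a
base learning rate of 1e-4 with batches of 1024 (both configurable; the
optimizer choice, early stopping on validation loss with patience 5, and
the 30-epoch default are this package's choices, exposed in `train()`).
The mask position for each record is a deterministic function of the
training seed, fixed across epochs.

The whole network, including backpropagation, is implemented directly in R
matrix operations. That choice is deliberate: integrated gradients needs
the gradient of the output with respect to the *input embeddings*, and
having one hand-audited computational core serve training, inference and
attribution keeps the three exactly consistent. The backward pass is
verified against central finite differences in the test suite. One
numerical caveat worth recording: at a freshly initialized model the
convolution biases are zero and many ReLU pre-activations sit exactly at
their kink, where the loss is not differentiable and finite-difference
checks disagree with any one-sided subgradient; the gradient check
therefore perturbs all parameters off the kink first.

The PAD token is pinned to the zero embedding vector and excluded from
gradient updates. This is not cosmetic: the zero vector doubles as the
integrated-gradients baseline, so the statement "the baseline is the
embedding of the padding token" holds exactly, and padded feature slots
receive exactly zero attribution.

### Defaults and desk-scale configuration

The default widths (residue embedding 32, LSTM hidden 64 per direction,
convolution channels 128/128/128 with kernels 3, categorical embeddings 16,
MLP 256/128) suit repertoires of tens of thousands of sequences. The
package's own tests, examples and the acceptance script run a reduced
configuration (8 / 16 / 32-32-32 / 8 / 64-32) on simulated repertoires of
about 2,000 records with 5-fold cross-validation, trained for up to 10
epochs at a learning rate of 3e-3 — problem sizes chosen so a full
desk-scale study runs in minutes while leaving the architecture untouched.

Fine-tuning (`fine_tune()`) continues training at 0.1 times the base
learning rate with the masked-residue task switched off — its loss
contribution is exactly zero on every step — and with no layer frozen.
Two parameter groups still receive exactly-zero gradients for data
reasons rather than freezing: the auxiliary head (its task produces no
gradient when disabled) and embedding rows of tokens absent from the
fine-tuning table (including the MASK token). Everything on the
classification path updates.

## Preprocessing rules

`read_airr()` ingests AIRR rearrangement TSVs, collapses allele-level calls
to the gene level (the `*NN` suffix is stripped), derives isotype from
`c_call` when needed, and logs dropped rows in the table's provenance.
Before training: HCDR3 lengths are restricted to 8–25; identity keys
(HCDR3, V, J, isotype) observed under more than one subset label are
removed entirely (`dedup_cross_subset()` — the tuple is exactly what the
model sees, so cross-subset duplicates are label conflicts); isotype
proportions can be rebalanced per subset by seeded down-sampling with
largest-remainder rounding (`balance_isotypes()`; targets are a required
study input, not a package default); and `split_dataset()` partitions
98/1/1 by seeded shuffle with floor-rule sizes, remainder to train.
`match_binders()` flags records whose HCDR3 equals a reference up to one
substitution at identical length — indels are deliberately not considered,
matching the single-substitution convention used throughout the package.

## Integrated gradients

For input features `V` (25 residue slots including padding, isotype, V
gene, J gene — 28 features, each an embedding vector) and the zero baseline
`V~`, the attribution of feature element `k` is the right-endpoint Riemann
approximation of the path integral

    IG_k = (V_k - V~_k) * (1/m) * sum_{p=1..m} dF[V~ + (p/m)(V - V~)] / dV_k

where `F` is the predicted-class softmax output. The per-feature score is
the mean of that feature's element-wise IG values. The right-endpoint rule
is kept as stated rather than replaced by the trapezoid rule; its O(1/m)
bias is visible in tests, where the completeness identity
`sum(IG) = F(V) - F(V~)` is approached monotonically as `m` grows and the
relative gap falls below 1% by `m = 300`. All `m` interpolation points are
evaluated as one batch, so attribution of a record costs one forward and
one backward pass at batch size `m`.

High-IG features are the top decile of scores. The pooling scope is
ambiguous in principle; the package pools per predicted-subset stratum (the
natural scope for per-subset composition summaries) and offers per-instance
pooling as an option. Exactly `ceiling(0.1 n)` items are flagged per
stratum; ties at the threshold are resolved by canonical feature order
(positions 1–25, isotype, V, J) and then result index, so selection is
deterministic and order-invariant. `paratope_overlap()` compares
externally supplied per-residue paratope probabilities (a residue is called
paratope only when its probability strictly exceeds 0.488) between high-IG
and other residues, with a seeded bootstrap whose resample counts are
configurable downward from publication scale.

## Saturation mutagenesis and the in-vivo comparison

`saturate()` rewrites each selected HCDR3 position to the 19 alternative
residues, holding isotype, V and J fixed — length is always preserved
because SHM is overwhelmingly substitutions. A prediction "flip" is a
change in the argmax subset. `flip_rate_comparison()` contrasts flips at
high-IG positions with a seeded random draw of equally many positions from
the rest of the sequence (topped up from the high-IG set when too few
non-high-IG positions exist, so the arms always have equal cardinality;
such records are flagged), aggregated per sequence length and compared by
paired t-test.
The in-vivo counterpart scans a labeled repertoire for same-V/J,
same-length record pairs at Hamming distance one with different subset
labels; each unordered pair increments a mutation group keyed by the
previous amino acid and position. "Previous" is taken from the
less-differentiated member (naive < memory < asc), since differentiation
order defines which state precedes; pairing conditions on V/J/length but
not isotype. `insilico_invivo_correlation()` is Spearman's rank correlation
between the two count tables over groups.

## Clonal grouping, trees and rerooting

Clones are single-linkage components within (V, J, junction-length)
buckets, linking two sequences when junction identity strictly exceeds 85%
(`(L - mismatches)/L > 0.85`, with a 1e-9 float tolerance so an exact-85%
pair never merges; unequal lengths never merge). Lineage filtering keeps
clones with at least 10 members and isotype switching — operationalized as
at least one IgG/IgA/IgE member, since a clone containing a switched member
has necessarily undergone switching — and down-samples clones above 200
members to 200 (the cap doubles as the target).

`build_tree_simple()` provides a deterministic neighbor-joining tree on
pairwise Hamming distances (midpoint-rooted, or rooted on a supplied
germline leaf) as plumbing; the rerooting operations accept any rooted
tree, and maximum-likelihood re-estimation after rerooting is intentionally
out of scope — rerooting here is topology-preserving, with an exported
chosen root for external ML tools.

A tree "needs rerooting" when an antigen-experienced leaf precedes a naive
leaf along the tree. Precedence is operationalized through divergence
depth: experienced leaf `a` precedes naive leaf `b` when the depth of `a`'s
divergence point (its parent node) is strictly smaller than `b`'s own
root-to-leaf depth. This makes a tree rooted on an experienced cell a
violation by construction (its divergence point is the root itself) while a
clean naive-to-experienced ladder is not. The new root is the least-mutated
naive leaf — SHM taken from the supplied counts — restricted to the
earliest timepoint present in the lineage when timepoints are given, with
exact ties broken by seeded uniform sampling and the entire decision
recorded in a report object. Rerooting drops the virtual germline tip if
present and preserves the unrooted split set exactly (asserted in tests by
bipartition enumeration). `evolution_order()` ranks leaves by root-to-leaf
path length with canonical tie-breaks, `order_rank_correlation()` compares
two trees by Spearman correlation over shared leaves, and
`thirds_distribution()` bins leaves into thirds of the `[0, max depth]`
divergence range.

## The synthetic-data generator

`simulate_repertoire()` emulates exactly the structure the classifier
exploits: subsets drawn from priors; germline HCDR3s of length 8–25 (peaked
at 15, the dominant human HCDR3 length) with uniform residues; Poisson SHM
loads of 0.3 / 4 / 6 substitutions for naive / memory / ASC, substituted
uniformly over the 19 alternatives (no indels, no hotspot motifs);
subset-conditional isotypes (naive mass entirely on IgM/IgD; switched
classes dominating memory and ASC); toy V/J gene sets; and optional planted
subset-discriminative motifs whose insertion probability sets the signal
strength for learnability experiments. What it does *not* emulate — real
V(D)J junctional statistics, SHM hotspots, clonal dependence between
records, isotype-subset correlations beyond the marginal tables — bounds
what passing tests show: they demonstrate that the pipeline recovers known
structure from data of this form, not that the classifier attains any
particular accuracy on real repertoires.

`simulate_lineage()` grows a random bifurcating tree from a naive IgM
germline: each branch adds Poisson(0.2) substitutions, subsets advance
naive → memory → asc with probability 0.35 per branch and never regress,
and isotypes switch monotonically. Branch lengths are mutations plus a
constant 0.5 offset so depths increase strictly along every path; the true
evolution order is the birth order of leaves, and leaves are binned into
three consecutive timepoints. The branch mutation mean of 0.2 on a
24-residue junction keeps every member pair connectable at the 85% clonal
threshold — the generator errors if its parameters break the single-clone
guarantee, rather than silently emitting a fragmented clone. Runs lacking
a naive (or an experienced) leaf — rare at these settings — relabel the
least- (most-) mutated leaf so the rerooting evaluation is always defined.
`misroot()` reroots the true tree on a seeded random experienced leaf,
creating the violation condition that the reroot pipeline is evaluated
against: across seeded lineages, the rank correlation between recovered and
true evolution order is higher for rerooted than for misrooted trees in the
median.

## Numerical choices and degenerate inputs

* Probability vectors from the softmax are clamped with `1e-12` inside
  cross-entropy; a uniform 3-class prediction scores exactly `ln 3`.
* `select_high_ig()` and `select_new_root()` document their tie rules
  (canonical feature order; seeded sampling) — nothing depends on hash or
  insertion order.
* Empty inputs propagate as empty results where that is meaningful (an
  empty AIRR file reads as an empty table; no qualifying in-vivo pair gives
  an empty count table); genuinely undefined requests error (correlation on
  fewer than 3 groups, rerooting without a naive leaf, trees from a single
  member).
* All stochastic operations take an explicit seed and restore the caller's
  RNG state, so library calls never perturb user scripts.

## Limitations

The classifier's accuracy on real repertoires depends on training data this
package does not ship; the simulator is a test harness, not a biological
model. Only heavy chains are modeled; full-length variable regions and
paired light chains are out of scope. The NJ tree builder is a convenience
stand-in — for publication-grade lineages, infer trees with a dedicated
phylogenetics tool and use the rerooting operations on the result.
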