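# bcrsort

Sequence-based classification of B-cell subsets from BCR heavy-chain
repertoires, with attribution, in-silico mutagenesis and lineage rerooting.

## The problem

During an immune response, naive B cells differentiate into memory B cells
and antibody-secreting cells (ASCs). The B-cell receptor records this
history in its own sequence: somatic hypermutation accumulates
substitutions and class switching replaces IgM/IgD with IgG/IgA/IgE.
`bcrsort` predicts, from a single heavy-chain rearrangement — the HCDR3
amino-acid sequence, the IGHV and IGHJ gene calls and the isotype — which
subset (naive, memory, ASC) the carrying cell belonged to, and uses that
prediction to reinterpret repertoire data that lacks cell phenotype:
bulk AIRR-seq tables, clonal lineages, longitudinal cohorts.

It is aimed at computational immunologists working with AIRR-style
rearrangement tables (immcantation-compatible TSVs).

## The model

The classifier is a recurrent-convolutional network

```
HCDR3 tokens (len ≤ 25, PAD) → embedding → 2-layer BiLSTM → 3 × conv1d + ReLU
                                         → global max-pool ┐
isotype, IGHV, IGHJ → categorical embeddings ──────────────┴→ 3-layer MLP
                                                              → softmax(naive, memory, asc)
```

trained with a masked-residue auxiliary task: one HCDR3 residue per
sequence is replaced by a MASK token and predicted back from the fused
feature vector, with total loss

L = CE(subset) + 0.05 · CE(masked residue),

Adam, base learning rate 10⁻⁴, batch size 1024 (all configurable). The
whole network — forward and backward — is implemented in base R matrix
operations, which gives the package exact gradients with respect to the
input embeddings. Those drive **integrated gradients** attribution

IG(Vᵢⱼ) = Σₖ (Vₖᵢⱼ − Ṽₖᵢⱼ) · (1/m) Σₚ ∂F[Ṽ + (p/m)(V − Ṽ)]/∂Vₖᵢⱼ,

computed from the zero-vector baseline Ṽ (identically the PAD embedding),
averaged per feature over its embedding elements. Downstream: top-decile
("high-IG") feature selection, in-silico saturation mutagenesis (19
substitutions per selected residue, length preserved), transfer learning
(0.1 × learning rate, no auxiliary task, nothing frozen), clonal grouping
(single linkage at junction identity > 85% within V/J/length), and
cell-subset-aware rerooting of lineage trees on the least-mutated naive
member. A synthetic-repertoire generator with known ground truth makes the
whole pipeline testable end to end; see the methods vignette
(`vignettes/bcrsort-methods.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(bcrsort)

spec <- synthetic_spec(
  n_records = 800,
  motifs = list(naive  = list(motif = "NAW", position = 5, prob = 0.9),
                memory = list(motif = "MKY", position = 5, prob = 0.9),
                asc    = list(motif = "DEH", position = 5, prob = 0.9)),
  seed = 42)
rep <- filter_hcdr3_length(simulate_repertoire(spec))

config <- bcr_config(residue_embed_dim = 8, lstm_hidden = 16,
                     cnn_channels = c(32, 32, 32), cat_embed_dim = 8,
                     mlp_widths = c(64, 32))
model <- train(rep, config, lr = 3e-3, batch_size = 128, epochs = 8, seed = 1)

heldout <- simulate_repertoire(synthetic_spec(n_records = 300,
                                              motifs = spec$motifs, seed = 99))
ev <- evaluate(model, heldout)
ev$accuracy
#> [1] 0.903
ev$confusion
#>         predicted
#> true     naive memory asc
#>   naive     99      3   1
#>   memory     0     82  11
#>   asc       10      4  90
```

Accuracy 0.90 on a held-out draw of the same synthetic conditions; the
confusion matrix rows are true subsets in the fixed order naive/memory/asc
(rows sum to the true class counts). Per-record predictions append three
probability columns and the argmax label:

```r
predict(model, heldout[1:3, ])[, c("isotype", "subset", "p_asc", "predicted_subset")]
#>   isotype subset     p_asc predicted_subset
#> 1 IgG     asc    0.993     asc
#> 2 IgM     memory 0.000100  memory
#> 3 IgM     naive  0.0160    naive
```

Attribution recovers what the model actually used — here the planted motif
region (positions 4–7) and the isotype:

```r
att <- integrated_gradients(model, heldout[1, ], m = 64)
round(sort(att$feature_scores, decreasing = TRUE)[1:5], 4)
#>   pos04 isotype   pos06   pos07   pos05
#>  0.0313  0.0306  0.0295  0.0205  0.0202
```

Rerooting a deliberately misrooted lineage on its least-mutated naive
member moves the recovered evolution order toward the truth (medians over
30 simulated lineages):

```r
rho <- sapply(1:30, function(s) {
  sim <- simulate_lineage(n_leaves = 20, seed = s)
  subsets <- setNames(sim$members$subset, sim$members$sequence_id)
  shm <- setNames(sim$members$shm_count, sim$members$sequence_id)
  bad <- misroot(sim$tree, subsets, seed = s)
  rpt <- select_new_root(bad, subsets, shm, seed = s)
  re <- reroot_tree(bad, rpt$chosen_root)
  c(misrooted = order_rank_correlation(bad, rank(sim$true_order)),
    rerooted = order_rank_correlation(re, rank(sim$true_order)))
})
round(apply(rho, 1, median), 3)
#> misrooted  rerooted
#>     0.220     0.418
```

A thin command-line front end over these functions ships at
`inst/cli/bcrsort.R` (subcommands `simulate`, `train`, `cv`, `finetune`,
`predict`, `attribute`, `mutate`, `clones`, `reroot`; every run writes a
manifest with its seed and configuration).

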