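# In-silico saturation mutagenesis at selected HCDR3 residues, prediction-
# flip accounting, and the in-vivo mutation-group correlation procedure.

mutate_seq <- function(seq, pos, aa) {
  substr(seq, pos, pos) <- aa
  seq
}

#' Saturation mutagenesis of one record at selected positions
#'
#' Replaces the residue at each selected HCDR3 position with the 19
#' alternative amino acids while holding isotype, V and J fixed, scores
#' every mutant with the model, and records whether the predicted subset
#' flipped relative to the parent. Sequence length is preserved (single
#' substitutions only; indels are rare in somatic hypermutation).
#'
#' @param model A trained `bcr_model`.
#' @param record One-row repertoire table.
#' @param positions Integer vector of 1-based HCDR3 positions to scan.
#' @return Tibble of mutants: `parent_id`, `position`, `from_aa`, `to_aa`,
#'   `parent_subset`, `mutant_subset`, `flipped` — exactly
#'   `19 * length(positions)` rows.
#' @export
saturate <- function(model, record, positions) {
  if (nrow(record) != 1) stop("saturate operates on a single record")
  seq <- record$hcdr3_aa
  L <- nchar(seq)
  if (any(positions < 1 | positions > L)) {
    stop("position out of range 1..", L)
  }
  parent_pred <- model_forward(model, record)$label
  muts <- dplyr::bind_rows(lapply(positions, function(p) {
    from <- substr(seq, p, p)
    tibble::tibble(position = p, from_aa = from,
                   to_aa = setdiff(AA_ALPHABET, from))
  }))
  mut_table <- record[rep(1, nrow(muts)), , drop = FALSE]
  mut_table$hcdr3_aa <- mapply(mutate_seq, mut_table$hcdr3_aa,
                               muts$position, muts$to_aa, USE.NAMES = FALSE)
  mut_table$sequence_id <- sprintf("%s_p%d%s", record$sequence_id,
                                   muts$position, muts$to_aa)
  pred <- model_forward(model, mut_table)$label
  tibble::tibble(parent_id = record$sequence_id,
                 position = muts$position, from_aa = muts$from_aa,
                 to_aa = muts$to_aa, parent_subset = parent_pred,
                 mutant_subset = pred,
                 flipped = pred != parent_pred)
}

#' Flip-rate comparison: high-IG versus random residues
#'
#' For every record, saturation mutagenesis is run twice: once at the
#' supplied high-IG residue positions and once at an equally sized, seeded
#' random selection drawn from the remaining positions (topped up from the
#' high-IG set when too few remain, which is flagged in `short_supply`).
#' Flip proportions are aggregated by sequence length and the two arms
#' compared with a paired t-test across lengths.
#'
#' @param model A trained `bcr_model`.
#' @param table Repertoire table.
#' @param high_ig_positions List parallel to rows of `table`: integer
#'   vectors of high-IG residue positions (e.g. from [select_high_ig()]).
#' @param seed Integer seed for the random arm.
#' @return List: `per_length` tibble (length, mean flip proportion per
#'   arm, n), `t_test` (paired t-test across lengths), `short_supply`
#'   (records with fewer non-high-IG positions than requested).
#' @export
flip_rate_comparison <- function(model, table, high_ig_positions, seed = 1L) {
  n <- nrow(table)
  stopifnot(length(high_ig_positions) == n)
  rows <- vector("list", n)
  short_supply <- integer(0)
  for (i in seq_len(n)) {
    rec <- table[i, , drop = FALSE]
    L <- nchar(rec$hcdr3_aa)
    hi <- high_ig_positions[[i]]
    hi <- hi[hi >= 1 & hi <= L]
    if (length(hi) == 0) next
    pool <- setdiff(seq_len(L), hi)
    k <- length(hi)
    rnd <- with_seed(seed + i, {
      take <- min(k, length(pool))
      out <- if (take > 0) sample(pool, take) else integer(0)
      if (take < k) {
        # not enough non-high-IG positions: top up from the high-IG set
        out <- c(out, sample(hi, k - take))
      }
      out
    })
    if (length(pool) < k) short_supply <- c(short_supply, i)
    flips_hi <- mean(saturate(model, rec, hi)$flipped)
    flips_rnd <- mean(saturate(model, rec, rnd)$flipped)
    rows[[i]] <- tibble::tibble(length = L, high_ig = flips_hi,
                                random = flips_rnd)
  }
  df <- dplyr::bind_rows(rows)
  per_length <- dplyr::summarise(
    dplyr::group_by(df, .data$length),
    n = dplyr::n(),
    high_ig = mean(.data$high_ig),
    random = mean(.data$random), .groups = "drop")
  tt <- if (nrow(per_length) >= 2 &&
            stats::sd(per_length$high_ig - per_length$random) > 0) {
    stats::t.test(per_length$high_ig, per_length$random, paired = TRUE)
  } else NULL
  list(per_length = per_length, t_test = tt, short_supply = short_supply)
}

#' Count in-silico subset alterations by mutation group
#'
#' Groups flipped mutants from [saturate()] output by the previous amino
#' acid and the mutation position, restricted to a given alteration pair
#' (either direction), and counts them.
#'
#' @param mutants Tibble of [saturate()] results (possibly row-bound over
#'   many parents); a `length` column is derived from the parent if absent.
#' @param lengths Optional integer vector of parent sequence lengths,
#'   parallel to the distinct `parent_id`s, used to annotate groups.
#' @param alteration Length-2 character vector, e.g. `c("memory", "asc")`.
#' @return Tibble: `from_aa`, `position`, `count`.
#' @export
insilico_alteration_counts <- function(mutants,
                                       alteration = c("memory", "asc"),
                                       lengths = NULL) {
  hit <- mutants$flipped &
    ((mutants$parent_subset == alteration[1] & mutants$mutant_subset == alteration[2]) |
     (mutants$parent_subset == alteration[2] & mutants$mutant_subset == alteration[1]))
  df <- mutants[hit, , drop = FALSE]
  dplyr::count(df, .data$from_aa, .data$position, name = "count")
}

#' Count in-vivo subset alterations by mutation group
#'
#' Scans a labeled repertoire for pairs of same-length records with
#' identical V/J genes whose HCDR3s differ at exactly one position and
#' which carry the two subset labels of the alteration pair. Each unordered
#' pair increments the mutation group keyed by the previous amino acid (the
#' residue of the less-differentiated member, naive < memory < asc) and the
#' mutation position. The repertoire should contain all three subsets to
#' reflect genuine in-vivo subset structure.
#'
#' @param table Labeled repertoire table.
#' @param alteration Length-2 character vector of subset labels.
#' @return Tibble: `from_aa`, `position`, `length`, `count` (empty when no
#'   qualifying pair exists).
#' @export
invivo_alteration_counts <- function(table, alteration = c("memory", "asc")) {
  if (!"subset" %in% names(table) || anyNA(table$subset)) {
    stop("invivo_alteration_counts requires subset labels")
  }
  alteration <- match.arg(alteration, SUBSET_LEVELS, several.ok = TRUE)
  rank <- match(table$subset, SUBSET_LEVELS)
  keep <- table$subset %in% alteration
  tab <- table[keep, , drop = FALSE]
  rank <- rank[keep]
  bucket <- paste(tab$v_gene, tab$j_gene, nchar(tab$hcdr3_aa), sep = "\r")
  rows <- list()
  for (b in unique(bucket)) {
    idx <- which(bucket == b)
    if (length(idx) < 2) next
    seqs <- tab$hcdr3_aa[idx]
    chm <- char_matrix(seqs)
    for (i in seq_len(length(idx) - 1)) {
      for (j in (i + 1):length(idx)) {
        if (tab$subset[idx[i]] == tab$subset[idx[j]]) next
        diffpos <- which(chm[i, ] != chm[j, ])
        if (length(diffpos) != 1) next
        # "previous" residue: the one on the less-differentiated member
        prev <- if (rank[idx[i]] <= rank[idx[j]]) chm[i, diffpos] else chm[j, diffpos]
        rows[[length(rows) + 1]] <- data.frame(
          from_aa = prev, position = diffpos, length = ncol(chm))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(from_aa = character(), position = integer(),
                          length = integer(), count = integer()))
  }
  dplyr::count(dplyr::bind_rows(rows), .data$from_aa, .data$position,
               .data$length, name = "count")
}

#' Correlation between in-silico and in-vivo mutation groups
#'
#' Spearman rank correlation between in-silico and in-vivo alteration
#' counts over mutation groups (previous amino acid, position) at a given
#' sequence length. Groups present in only one arm are taken as count 0 in
#' the other.
#'
#' @param insilico Tibble from [insilico_alteration_counts()].
#' @param invivo Tibble from [invivo_alteration_counts()].
#' @param length Sequence length to restrict the in-vivo groups to
#'   (NULL keeps all).
#' @return Spearman's rho.
#' @export
insilico_invivo_correlation <- function(insilico, invivo, length = NULL) {
  if (!is.null(length) && "length" %in% names(invivo)) {
    invivo <- invivo[invivo$length == length, , drop = FALSE]
  }
  merged <- merge(insilico[, c("from_aa", "position", "count")],
                  invivo[, c("from_aa", "position", "count")],
                  by = c("from_aa", "position"), all = TRUE,
                  suffixes = c("_insilico", "_invivo"))
  merged[is.na(merged)] <- 0
  usable <- merged$count_insilico > 0 | merged$count_invivo > 0
  if (sum(usable) < 3) {
    stop("fewer than 3 mutation groups with nonzero counts; cannot correlate")
  }
  stats::cor(merged$count_insilico[usable], merged$count_invivo[usable],
             method = "spearman")
}
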