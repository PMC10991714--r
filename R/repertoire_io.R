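# Reading AIRR rearrangement tables and the preprocessing / filtering rules
# applied before training or analysis.

#' Construct a BCR repertoire table
#'
#' A repertoire table is a tibble with one row per heavy-chain rearrangement
#' and at least the columns `sequence_id`, `hcdr3_aa`, `v_gene`, `j_gene`,
#' `isotype`. Optional columns: `subset` (one of `r toString(SUBSET_LEVELS)`),
#' `hcdr3_nt`, `shm_count`, `subject_id`, `timepoint`, `timepoint_order`.
#' Provenance (source file, applied filters, drop counts) is carried in the
#' `"provenance"` attribute.
#'
#' @param df Data frame with the columns above.
#' @param provenance Optional list of provenance entries.
#' @return A `bcr_repertoire` tibble.
#' @export
bcr_repertoire <- function(df, provenance = list()) {
  df <- tibble::as_tibble(df)
  required <- c("sequence_id", "hcdr3_aa", "v_gene", "j_gene", "isotype")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sequence_id)) {
    stop("sequence_id must be unique within a repertoire table")
  }
  if (nrow(df) > 0) {
    if (any(!nzchar(df$hcdr3_aa)) || any(df$hcdr3_aa != toupper(df$hcdr3_aa))) {
      stop("hcdr3_aa must be non-empty and uppercase")
    }
    bad_iso <- setdiff(unique(df$isotype), ISOTYPE_LEVELS)
    if (length(bad_iso) > 0) {
      stop("unknown isotype(s): ", paste(bad_iso, collapse = ", "))
    }
    if ("subset" %in% names(df)) {
      bad <- setdiff(unique(stats::na.omit(df$subset)), SUBSET_LEVELS)
      if (length(bad) > 0) stop("unknown subset label(s): ", paste(bad, collapse = ", "))
    }
    if ("shm_count" %in% names(df) &&
        any(stats::na.omit(df$shm_count) < 0)) {
      stop("shm_count must be non-negative")
    }
  }
  attr(df, "provenance") <- provenance
  class(df) <- unique(c("bcr_repertoire", class(df)))
  df
}

#' Retrieve the provenance log of a repertoire table
#' @param table A repertoire table.
#' @return List of provenance entries.
#' @export
provenance <- function(table) attr(table, "provenance") %||% list()

add_provenance <- function(table, entry) {
  attr(table, "provenance") <- c(provenance(table), list(entry))
  table
}

# Collapse an allele-level call ("IGHV1-2*02") to the gene level ("IGHV1-2").
# Unknown/novel strings are kept verbatim (mapped to OOV downstream).
strip_allele <- function(calls) {
  sub("\\*.*$", "", calls)
}

# Map a constant-region call (c_call, e.g. "IGHM") or an isotype label to
# the canonical IgM/IgD/IgG/IgA/IgE labels; NA when unresolvable.
normalize_isotype <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  canon <- ISOTYPE_LEVELS
  idx <- match(toupper(x), toupper(canon))
  out[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  # constant-region gene calls: IGHM, IGHD, IGHG1, IGHA2, IGHE ...
  cc <- toupper(substr(x, 1, 4))
  hit <- is.na(out) & cc %in% c("IGHM", "IGHD", "IGHG", "IGHA", "IGHE")
  out[hit] <- c(IGHM = "IgM", IGHD = "IgD", IGHG = "IgG",
                IGHA = "IgA", IGHE = "IgE")[cc[hit]]
  out
}

#' Read an AIRR rearrangement TSV into a repertoire table
#'
#' Reads a tab-separated rearrangement file following the AIRR schema and
#' builds one [bcr_repertoire()] record per parseable row. Allele-level
#' V/J calls are collapsed to the gene level (the `*NN` allele suffix is
#' stripped); the isotype is taken from an `isotype` column or derived from
#' `c_call`. Rows whose required fields cannot be parsed are dropped and
#' counted in the table's provenance.
#'
#' @param path Path to a TSV file.
#' @param column_map Optional named character vector mapping the canonical
#'   names (`junction_aa`, `v_call`, `j_call`, `isotype`, `subset`,
#'   `sequence_id`, ...) to the file's column names, for dialects.
#' @return A `bcr_repertoire` tibble; empty file gives an empty table.
#' @export
read_airr <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  cols <- function(canonical, alternatives = character()) {
    if (!is.null(column_map) && canonical %in% names(column_map)) {
      nm <- unname(column_map[[canonical]])
      if (!nm %in% names(raw)) stop("column_map names a missing column: ", nm)
      return(nm)
    }
    hit <- intersect(c(canonical, alternatives), names(raw))
    if (length(hit) > 0) hit[1] else NA_character_
  }
  if (nrow(raw) == 0) {
    return(bcr_repertoire(
      tibble::tibble(sequence_id = character(), hcdr3_aa = character(),
                     v_gene = character(), j_gene = character(),
                     isotype = character()),
      provenance = list(list(source = path, n_read = 0L, n_dropped = 0L))))
  }
  junc_col <- cols("junction_aa", c("cdr3_aa", "hcdr3_aa"))
  v_col <- cols("v_call", "v_gene")
  j_col <- cols("j_call", "j_gene")
  iso_col <- cols("isotype", "c_call")
  for (nm in c(junction_aa = junc_col, v_call = v_col, j_call = j_col,
               isotype = iso_col)) {
    if (is.na(nm)) {
      need <- names(which(c(junction_aa = junc_col, v_call = v_col,
                            j_call = j_col, isotype = iso_col) == nm))
      stop("required column not resolvable: ",
           paste(need, collapse = ", "), " (use column_map)")
    }
  }
  id_col <- cols("sequence_id")
  out <- tibble::tibble(
    sequence_id = if (!is.na(id_col)) raw[[id_col]] else sprintf("seq%06d", seq_len(nrow(raw))),
    hcdr3_aa = toupper(raw[[junc_col]]),
    v_gene = strip_allele(raw[[v_col]]),
    j_gene = strip_allele(raw[[j_col]]),
    isotype = normalize_isotype(raw[[iso_col]])
  )
  opt <- c(subset = "subset", hcdr3_nt = "junction", shm_count = "shm_count",
           subject_id = "subject_id", timepoint = "timepoint",
           timepoint_order = "timepoint_order")
  for (canonical in names(opt)) {
    nm <- cols(canonical, unname(opt[canonical]))
    if (!is.na(nm)) out[[canonical]] <- raw[[nm]]
  }
  if ("shm_count" %in% names(out)) out$shm_count <- as.integer(out$shm_count)
  if ("timepoint_order" %in% names(out)) {
    out$timepoint_order <- as.integer(out$timepoint_order)
  }
  ok <- !is.na(out$hcdr3_aa) & nzchar(out$hcdr3_aa) &
    grepl("^[A-Z]+$", out$hcdr3_aa) &
    !is.na(out$v_gene) & nzchar(out$v_gene) &
    !is.na(out$j_gene) & nzchar(out$j_gene) &
    !is.na(out$isotype)
  dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  bcr_repertoire(out, provenance = list(list(
    source = path, n_read = nrow(raw), n_dropped = as.integer(dropped))))
}

#' Write a repertoire table as an AIRR-style TSV
#'
#' Writes the table with AIRR column names (`junction_aa`, `v_call`,
#' `j_call`) plus any extra columns, and the provenance log as a JSON
#' sidecar (`<path>.provenance.json`).
#'
#' @param table Repertoire table.
#' @param path Output TSV path.
#' @param sidecar Write the provenance sidecar? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_airr <- function(table, path, sidecar = TRUE) {
  out <- tibble::as_tibble(table)
  names(out)[names(out) == "hcdr3_aa"] <- "junction_aa"
  names(out)[names(out) == "v_gene"] <- "v_call"
  names(out)[names(out) == "j_gene"] <- "j_call"
  readr::write_tsv(out, path, progress = FALSE)
  if (sidecar) {
    jsonlite::write_json(provenance(table), paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Filter records by HCDR3 length
#'
#' Retains records whose HCDR3 amino-acid length lies in
#' `[min_len, max_len]` (bounds inclusive), preserving order. The defaults
#' 8–25 are the length window the classifier operates on.
#'
#' @param table Repertoire table.
#' @param min_len,max_len Inclusive length bounds.
#' @return Filtered repertoire table.
#' @export
filter_hcdr3_length <- function(table, min_len = 8L, max_len = 25L) {
  stopifnot(min_len <= max_len)
  len <- nchar(table$hcdr3_aa)
  keep <- len >= min_len & len <= max_len
  out <- table[keep, , drop = FALSE]
  add_provenance(out, list(filter = "hcdr3_length", min = min_len,
                           max = max_len, n_dropped = sum(!keep)))
}

dedup_key <- function(table) {
  paste(table$hcdr3_aa, table$v_gene, table$j_gene, table$isotype, sep = "\r")
}

#' Remove sequences duplicated across B-cell subsets
#'
#' A sequence identity key — the full input tuple (HCDR3, V gene, J gene,
#' isotype) — observed under two or more distinct subset labels creates a
#' label conflict for training; all copies of such keys are removed.
#' Within-subset duplicates are retained.
#'
#' @param table Labeled repertoire table (`subset` column required).
#' @return Filtered repertoire table.
#' @export
dedup_cross_subset <- function(table) {
  if (!"subset" %in% names(table) || anyNA(table$subset)) {
    stop("dedup_cross_subset requires subset labels on every record")
  }
  key <- dedup_key(table)
  n_subsets <- tapply(table$subset, key, function(s) length(unique(s)))
  conflicted <- names(n_subsets)[n_subsets >= 2]
  keep <- !(key %in% conflicted)
  out <- table[keep, , drop = FALSE]
  add_provenance(out, list(filter = "dedup_cross_subset",
                           n_dropped = sum(!keep),
                           n_conflicted_keys = length(conflicted)))
}

#' Balance isotype proportions within each subset by down-sampling
#'
#' Down-samples records per subset (seeded, without replacement) so the
#' realized isotype proportions match the supplied targets as closely as
#' integer counts allow, maximizing the total number of retained records.
#' Integer rounding uses the largest-remainder method.
#'
#' @param table Labeled repertoire table.
#' @param targets Named list: `targets[[subset]]` is a named numeric vector
#'   of isotype proportions summing to 1. There is no default: target
#'   proportions are a study design input.
#' @param seed Integer seed making the down-sampling reproducible.
#' @return Balanced repertoire table.
#' @export
balance_isotypes <- function(table, targets, seed) {
  if (!"subset" %in% names(table)) stop("balance_isotypes requires subset labels")
  keep_idx <- integer(0)
  warnings_log <- list()
  for (ss in names(targets)) {
    p <- targets[[ss]]
    if (abs(sum(p) - 1) > 1e-9) stop("target proportions for ", ss, " must sum to 1")
    rows <- which(table$subset == ss)
    if (length(rows) == 0) next
    avail <- table(factor(table$isotype[rows], levels = names(p)))
    missing <- names(p)[p > 0 & avail == 0]
    if (length(missing) > 0) {
      warning("subset ", ss, ": no records with isotype ",
              paste(missing, collapse = ", "), "; scaling remaining targets")
      warnings_log <- c(warnings_log, list(list(subset = ss, absent = missing)))
      p <- p[!(names(p) %in% missing)]
      p <- p / sum(p)
      avail <- avail[names(p)]
    }
    # largest feasible total, then largest-remainder apportionment
    pos <- p > 0
    n_total <- if (any(pos)) floor(min(as.numeric(avail[pos]) / p[pos])) else 0
    alloc <- largest_remainder(n_total, p)
    while (any(alloc > avail) && n_total > 0) {
      n_total <- n_total - 1
      alloc <- largest_remainder(n_total, p)
    }
    names(alloc) <- names(p)
    for (iso in names(p)) {
      cand <- rows[table$isotype[rows] == iso]
      k <- alloc[[iso]]
      if (k >= length(cand)) {
        keep_idx <- c(keep_idx, cand)
      } else {
        sel <- with_seed(seed + match(ss, names(targets)) * 131L +
                           match(iso, ISOTYPE_LEVELS),
                         sample(cand, k))
        keep_idx <- c(keep_idx, sel)
      }
    }
  }
  # subsets without a target entry are passed through untouched
  keep_idx <- c(keep_idx, which(!(table$subset %in% names(targets))))
  out <- table[sort(keep_idx), , drop = FALSE]
  add_provenance(out, list(filter = "balance_isotypes", seed = seed,
                           n_dropped = nrow(table) - nrow(out),
                           scaling = warnings_log))
}

#' Split a repertoire into train / validation / test partitions
#'
#' Seeded shuffle followed by a contiguous partition. Partition sizes are
#' `floor(n * fraction)` with the remainder assigned to the training split,
#' so the three partitions are disjoint and cover the input.
#'
#' @param table Repertoire table.
#' @param fractions Length-3 numeric summing to 1; default `c(.98, .01, .01)`.
#' @param seed Integer seed.
#' @return Named list of repertoire tables: `train`, `validation`, `test`.
#' @export
split_dataset <- function(table, fractions = c(0.98, 0.01, 0.01), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  n <- nrow(table)
  if (n < 3 && all(fractions > 0)) {
    stop("need at least 3 records to populate three non-empty partitions")
  }
  sizes <- floor(n * fractions)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  perm <- with_seed(seed, sample.int(n))
  bounds <- cumsum(sizes)
  idx <- list(
    train = perm[seq_len(sizes[1])],
    validation = if (sizes[2] > 0) perm[(bounds[1] + 1):bounds[2]] else integer(0),
    test = if (sizes[3] > 0) perm[(bounds[2] + 1):bounds[3]] else integer(0)
  )
  lapply(idx, function(i) table[sort(i), , drop = FALSE])
}

#' Flag records matching a binder reference list
#'
#' A record is a binder match when some reference HCDR3 of identical length
#' differs from it at no more than `max_mismatch` positions (Hamming
#' distance; indels are not considered). The default of one allowed
#' mismatch follows the single-substitution convention used throughout.
#'
#' @param table Repertoire table.
#' @param references Character vector of reference HCDR3 amino-acid strings.
#' @param max_mismatch Maximum allowed mismatches; default 1.
#' @return Logical vector, one flag per record.
#' @export
match_binders <- function(table, references, max_mismatch = 1L) {
  if (length(references) == 0) stop("references must be non-empty")
  refs_by_len <- split(references, nchar(references))
  vapply(table$hcdr3_aa, function(s) {
    refs <- refs_by_len[[as.character(nchar(s))]]
    if (is.null(refs)) return(FALSE)
    any(hamming_vec(s, refs) <= max_mismatch)
  }, logical(1), USE.NAMES = FALSE)
}
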