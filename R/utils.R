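# Shared low-level helpers: amino-acid alphabet, Hamming utilities, seeding.

#' The 20-letter amino-acid alphabet used throughout
#'
#' Standard one-letter codes in alphabetical order. Residue token indices,
#' the masked-residue auxiliary vocabulary and saturation mutagenesis all
#' use this ordering.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Cell-subset class labels in canonical order
#'
#' The fixed class order (naive, memory, asc) used for model outputs,
#' confusion matrices and everywhere a subset index appears.
#'
#' @format Character vector of length 3.
#' @export
SUBSET_LEVELS <- c("naive", "memory", "asc")

#' Heavy-chain isotype labels
#' @format Character vector of length 5.
#' @export
ISOTYPE_LEVELS <- c("IgM", "IgD", "IgG", "IgA", "IgE")

# isotypes counted as class-switched (antigen-experienced signature)
SWITCHED_ISOTYPES <- c("IgG", "IgA", "IgE")

# Hamming distance between two equal-length strings.
hamming1 <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Hamming distances between one string and a character vector of equal-length
# strings. Returns integer vector.
hamming_vec <- function(a, bs) {
  ai <- utf8ToInt(a)
  vapply(bs, function(b) sum(utf8ToInt(b) != ai), integer(1), USE.NAMES = FALSE)
}

# Character matrix (n x L) from equal-length strings; errors on ragged input.
char_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must share a common length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = length(seqs), byrow = TRUE)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Largest-remainder apportionment of n into parts proportional to p (sums to 1).
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
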