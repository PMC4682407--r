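# Internal: raw overlapping-window dipeptide counts (n x 400) plus the
# per-sequence window count L - 1. Keeping counts integral lets scoring
# divide once, so e.g. a constant scorecard scores exactly its constant.
dpc_counts <- function(residues) {
  check_canonical(residues)
  L <- nchar(residues)
  if (any(L < 2L)) {
    abort("Dipeptide composition requires sequences of length >= 2.")
  }
  counts <- matrix(0, nrow = length(residues), ncol = 400L,
                   dimnames = list(names(residues), DIPEPTIDES))
  for (k in seq_along(residues)) {
    s <- match(strsplit(residues[k], "", fixed = TRUE)[[1]], AA_ALPHABET)
    idx <- (head(s, -1L) - 1L) * 20L + tail(s, -1L)
    counts[k, ] <- tabulate(idx, nbins = 400L)
  }
  list(counts = counts, windows = L - 1L)
}

# Internal: n x 400 matrix of dipeptide relative frequencies, one row per
# sequence. Overlapping windows; entry (i,j) = N_ij / (L - 1).
dpc_matrix <- function(residues) {
  cc <- dpc_counts(residues)
  cc$counts / cc$windows
}

# Internal: n x 20 matrix of amino-acid relative frequencies.
aac_matrix <- function(residues) {
  check_canonical(residues)
  L <- nchar(residues)
  if (any(L < 1L)) {
    abort("Amino-acid composition requires non-empty sequences.")
  }
  out <- matrix(0, nrow = length(residues), ncol = 20L,
                dimnames = list(names(residues), AA_ALPHABET))
  for (k in seq_along(residues)) {
    s <- match(strsplit(residues[k], "", fixed = TRUE)[[1]], AA_ALPHABET)
    out[k, ] <- tabulate(s, nbins = 20L) / L[k]
  }
  out
}

# Internal: mean class composition as a plain named vector.
mean_comp_vec <- function(residues,
                          kind = c("dipeptide", "amino_acid"),
                          pooling = c("mean_of_sequences", "pooled_counts")) {
  kind <- match.arg(kind)
  pooling <- match.arg(pooling)
  if (length(residues) == 0L) abort("Empty sequence set.")
  L <- nchar(residues)
  if (pooling == "mean_of_sequences") {
    m <- if (kind == "dipeptide") dpc_matrix(residues) else aac_matrix(residues)
    return(colMeans(m))
  }
  # pooled_counts: sum raw counts across sequences, divide once
  if (kind == "dipeptide") {
    if (any(L < 2L)) abort("Dipeptide composition requires sequences of length >= 2.")
    counts <- numeric(400L)
    for (r in residues) {
      s <- match(strsplit(r, "", fixed = TRUE)[[1]], AA_ALPHABET)
      idx <- (head(s, -1L) - 1L) * 20L + tail(s, -1L)
      counts <- counts + tabulate(idx, nbins = 400L)
    }
    setNames(counts / sum(L - 1L), DIPEPTIDES)
  } else {
    if (any(L < 1L)) abort("Amino-acid composition requires non-empty sequences.")
    counts <- numeric(20L)
    for (r in residues) {
      s <- match(strsplit(r, "", fixed = TRUE)[[1]], AA_ALPHABET)
      counts <- counts + tabulate(s, nbins = 20L)
    }
    setNames(counts / sum(L), AA_ALPHABET)
  }
}

#' Dipeptide composition of protein sequences
#'
#' For each sequence, computes the 400-dimensional vector of relative
#' frequencies of overlapping ordered residue pairs: the entry for dipeptide
#' (i, j) is `N_ij / (L - 1)`, where `N_ij` counts positions at which residue
#' i is immediately followed by residue j and L is the sequence length.
#' Entries are non-negative and sum to 1 for every sequence.
#'
#' @param seqs A sequence tibble (columns `id`, `residues`) as returned by
#'   [read_fasta()], or a character vector of canonical sequences.
#' @return A long tibble with columns `id`, `dipeptide` (all 400, in
#'   canonical order per sequence) and `frequency`.
#' @examples
#' dipeptide_composition(c(s1 = "LFLF")) |> dplyr::filter(frequency > 0)
#' @export
dipeptide_composition <- function(seqs) {
  m <- dpc_matrix(seq_residues(seqs))
  tibble(
    id = rep(rownames(m), each = 400L),
    dipeptide = rep(DIPEPTIDES, times = nrow(m)),
    frequency = as.vector(t(m))
  )
}

#' Amino-acid composition of protein sequences
#'
#' The entry for residue r is `count(r) / L`.
#'
#' @inheritParams dipeptide_composition
#' @return A long tibble with columns `id`, `residue` (all 20 per sequence)
#'   and `frequency`.
#' @export
amino_acid_composition <- function(seqs) {
  m <- aac_matrix(seq_residues(seqs))
  tibble(
    id = rep(rownames(m), each = 20L),
    residue = rep(AA_ALPHABET, times = nrow(m)),
    frequency = as.vector(t(m))
  )
}

#' Mean composition of a labelled sequence set
#'
#' Aggregates per-sequence compositions into one class-level vector. Under
#' `"mean_of_sequences"` (default) every sequence contributes equally: the
#' result is the unweighted mean of per-sequence composition vectors, so
#' class differences are not dominated by a few long sequences. Under
#' `"pooled_counts"` raw counts are pooled first:
#' `sum(N_ij) / sum(L_s - 1)` for dipeptides, `sum(count) / sum(L)` for
#' amino acids. Both return vectors that sum to 1.
#'
#' @inheritParams dipeptide_composition
#' @param kind `"dipeptide"` (400 entries) or `"amino_acid"` (20 entries).
#' @param pooling `"mean_of_sequences"` or `"pooled_counts"`.
#' @return A tibble with columns `dipeptide` (or `residue`) and `frequency`.
#' @export
mean_class_composition <- function(seqs,
                                   kind = c("dipeptide", "amino_acid"),
                                   pooling = c("mean_of_sequences", "pooled_counts")) {
  kind <- match.arg(kind)
  v <- mean_comp_vec(seq_residues(seqs), kind, match.arg(pooling))
  if (kind == "dipeptide") {
    tibble(dipeptide = names(v), frequency = unname(v))
  } else {
    tibble(residue = names(v), frequency = unname(v))
  }
}
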