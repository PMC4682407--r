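# Canonical residue alphabet and dipeptide ordering used everywhere.
# Dipeptides are ordered lexicographically with the first residue major:
# AA, AC, AD, ..., YY.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

DIPEPTIDES <- paste0(rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, times = 20L))

#' Canonical amino-acid and dipeptide orderings
#'
#' The 20-letter amino-acid alphabet (alphabetical one-letter codes) and the
#' 400 ordered dipeptides (first residue major: AA, AC, ..., YY) that fix the
#' column order of every composition vector and scorecard in the package.
#'
#' @return A character vector of length 20 (`amino_acids()`) or 400
#'   (`dipeptides()`).
#' @examples
#' head(amino_acids())
#' head(dipeptides())
#' @export
amino_acids <- function() AA_ALPHABET

#' @rdname amino_acids
#' @export
dipeptides <- function() DIPEPTIDES

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Accept either a sequence tibble (id/residues columns) or a character vector
# of residue strings; return a character vector named by sequence id.
seq_residues <- function(x, arg = "seqs") {
  if (is.data.frame(x)) {
    if (!all(c("id", "residues") %in% names(x))) {
      abort(sprintf("`%s` must have columns `id` and `residues`.", arg))
    }
    return(setNames(as.character(x$residues), as.character(x$id)))
  }
  if (is.character(x)) {
    if (length(x) == 0L) return(setNames(character(0), character(0)))
    ids <- names(x) %||% paste0("seq", seq_along(x))
    ids[ids == ""] <- paste0("seq", seq_along(x))[ids == ""]
    return(setNames(unname(x), ids))
  }
  abort(sprintf("`%s` must be a data frame of sequences or a character vector.", arg))
}

check_canonical <- function(residues, arg = "seqs") {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), residues)
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains non-canonical residues in %d sequence(s); validate with read_fasta() or clean first.",
      arg, sum(bad)
    ))
  }
  invisible(residues)
}
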