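#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a sequence tibble, enforcing the
#' 20-letter canonical alphabet `ACDEFGHIKLMNPQRSTVWY`. Input is
#' case-insensitive; residues are stored upper-case. Records whose sequences
#' contain other characters (`B`, `Z`, `X`, `U`, `O`, `J`, `*`, gaps, ...)
#' are handled according to `policy`:
#'
#' * `"skip"` (default): offending records are dropped, each with a message.
#'   Mirrors the common practice of excluding sequences with uncommon amino
#'   acids from training sets.
#' * `"strict"`: any non-canonical residue is an error.
#' * `"mask"`: non-canonical characters are removed from the sequence, with a
#'   message; a record left empty is dropped.
#'
#' Records with an empty sequence are an error under `"strict"` and are
#' dropped (with a message) otherwise.
#'
#' @param path Path to a FASTA file.
#' @param policy One of `"skip"`, `"strict"`, `"mask"`.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly `""`) and
#'   `residues` (upper-case canonical sequence), in file order.
#' @seealso [write_fasta()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "ACDE", ">s2", "acxe"), fa)
#' read_fasta(fa)             # s2 dropped
#' read_fasta(fa, "mask")     # s2 kept as ACE
#' @export
read_fasta <- function(path, policy = c("skip", "strict", "mask")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(sprintf("FASTA file '%s' contains no records.", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))

  keep <- rep(TRUE, length(ids))
  pattern <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
  for (k in seq_along(ids)) {
    r <- residues[k]
    if (!nzchar(ids[k])) {
      if (policy == "strict") abort(sprintf("Record %d has an empty id.", k))
      inform(sprintf("Dropping record %d: empty id.", k))
      keep[k] <- FALSE
      next
    }
    bad <- unique(strsplit(gsub(sprintf("[%s]", paste(AA_ALPHABET, collapse = "")), "", r), "")[[1]])
    if (length(bad) > 0L) {
      if (policy == "strict") {
        abort(sprintf(
          "Record '%s' contains non-canonical residue(s): %s",
          ids[k], paste(bad, collapse = ", ")
        ))
      }
      if (policy == "skip") {
        inform(sprintf(
          "Excluding '%s': non-canonical residue(s) %s",
          ids[k], paste(bad, collapse = ", ")
        ))
        keep[k] <- FALSE
        next
      }
      # mask
      r <- gsub(pattern, "", r)
      inform(sprintf(
        "Masked %d non-canonical character(s) in '%s'",
        nchar(residues[k]) - nchar(r), ids[k]
      ))
      residues[k] <- r
    }
    if (!nzchar(r)) {
      if (policy == "strict") abort(sprintf("Record '%s' has an empty sequence.", ids[k]))
      inform(sprintf("Dropping '%s': empty sequence.", ids[k]))
      keep[k] <- FALSE
    }
  }
  tibble(
    id = ids[keep],
    description = desc[keep],
    residues = unname(residues[keep])
  )
}

#' Write a sequence tibble to a FASTA file
#'
#' Writes validated sequences as multi-record FASTA wrapped at 60 columns.
#' `read_fasta(write_fasta(x, path))` reproduces `id` and `residues` exactly.
#'
#' @param seqs A sequence tibble with columns `id` and `residues`
#'   (`description` optional), or a named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  res <- seq_residues(seqs)
  check_canonical(res)
  if (is.data.frame(seqs) && "description" %in% names(seqs)) {
    hdr <- ifelse(nzchar(seqs$description),
      paste(names(res), seqs$description),
      names(res)
    )
  } else {
    hdr <- names(res)
  }
  set <- Biostrings::BStringSet(unname(res))
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
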