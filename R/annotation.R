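# Per-residue propensity tracks, sliding-window profiles, heat-map export
# and PDB B-factor annotation.

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

# Per-position values for a single residue string.
track_values <- function(residues, card, source) {
  s <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (source == "aa") {
    return(unname(card$aa_scores[s]))
  }
  L <- length(s)
  if (L < 2L) abort("Dipeptide tracks need sequences of length >= 2.")
  d <- unname(card$dipeptide_scores[paste0(head(s, -1L), tail(s, -1L))])
  # position i averages its left and right windows where both exist
  left <- c(NA, d)
  right <- c(d, NA)
  rowMeans(cbind(left, right), na.rm = TRUE)
}

#' Per-residue propensity track
#'
#' Assigns every residue of each sequence a propensity value from a
#' scorecard. With `source = "aa"` the residue's amino-acid score is used.
#' With `source = "dipeptide"` position i receives the mean of the scores
#' of the two dipeptide windows covering it (`(i-1, i)` and `(i, i+1)`);
#' terminal residues use their single defined window. Values therefore
#' always lie within the card's score range.
#'
#' @param seqs Sequence tibble or character vector.
#' @param card A `scorecard`.
#' @param source `"aa"` or `"dipeptide"`.
#' @return A tibble of class `residue_track` with columns `sequence_id`,
#'   `position` (1-based), `residue`, `value`.
#' @export
residue_track <- function(seqs, card, source = c("aa", "dipeptide")) {
  source <- match.arg(source)
  stopifnot(inherits(card, "scorecard"))
  res <- seq_residues(seqs)
  check_canonical(res)
  out <- purrr::map2_dfr(names(res), res, function(id, r) {
    v <- track_values(r, card, source)
    tibble(
      sequence_id = id,
      position = seq_len(nchar(r)),
      residue = strsplit(r, "", fixed = TRUE)[[1]],
      value = v
    )
  })
  class(out) <- c("residue_track", class(out))
  attr(out, "source") <- source
  out
}

#' Sliding-window profile of a residue track
#'
#' Centered moving average over full windows only (the hydropathy-plot
#' convention): the profile is defined for positions `(w+1)/2` through
#' `L - (w-1)/2`, i.e. has `L - w + 1` points per sequence. The default
#' window of 19 residues follows the classical hydropathy-plot convention
#' for locating membrane-spanning segments.
#'
#' @param track A `residue_track` tibble (or any tibble with `sequence_id`,
#'   `position`, `value`).
#' @param window Odd window width, at most the shortest sequence length.
#' @return A tibble of class `scm_profile` with columns `sequence_id`,
#'   `position` (window centre) and `value` (window mean).
#' @export
sliding_profile <- function(track, window = 19L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  out <- track |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::group_modify(function(d, key) {
      L <- nrow(d)
      if (window > L) {
        abort(sprintf(
          "Window %d exceeds the length (%d) of sequence '%s'.",
          window, L, key$sequence_id
        ))
      }
      # sum-then-divide so a constant track yields exactly that constant
      v <- as.vector(stats::filter(d$value[order(d$position)], rep(1, window), sides = 2)) / window
      keep <- !is.na(v)
      tibble(position = sort(d$position)[keep], value = v[keep])
    }) |>
    dplyr::ungroup()
  class(out) <- c("scm_profile", class(out))
  attr(out, "window") <- window
  out
}

#' Dipeptide score heat-map matrix
#'
#' @param card A `scorecard`.
#' @param path Optional path; if given, the matrix is written as a TSV with
#'   row names (rows = first residue, columns = second residue).
#' @return A 20 x 20 numeric matrix in canonical residue order; rows index
#'   the first residue of the dipeptide.
#' @export
heatmap_table <- function(card, path = NULL) {
  stopifnot(inherits(card, "scorecard"))
  m <- matrix(card$dipeptide_scores[DIPEPTIDES], nrow = 20L, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  if (!is.null(path)) {
    write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  }
  m
}

#' Annotate a PDB structure with propensity scores in the B-factor column
#'
#' Writes a copy of a PDB file in which the temperature-factor field
#' (columns 61-66) of every `ATOM` record carries the residue's track value
#' divided by 10 (so scores map to the 0-100 B-factor range, format
#' `%6.2f`), ready for colouring in a molecular viewer. `HETATM` atoms and
#' residues that cannot be mapped to the 20-letter alphabet get 0.00 and
#' are counted in the summary. All other bytes of every record — including
#' coordinates — are preserved exactly; a `REMARK` line documenting the
#' scaling is prepended.
#'
#' @param pdb_in,pdb_out Input and output PDB paths.
#' @param card A `scorecard`.
#' @param source `"aa"` or `"dipeptide"` track values (see
#'   [residue_track()]). A chain with a single standard residue falls back
#'   to its amino-acid score under the dipeptide source.
#' @return A one-row tibble: `n_atoms` (ATOM/HETATM records rewritten),
#'   `n_residues` (standard residues annotated), `n_unmapped_residues`,
#'   `n_unmapped_atoms`.
#' @export
annotate_structure <- function(pdb_in, pdb_out, card,
                               source = c("aa", "dipeptide")) {
  source <- match.arg(source)
  stopifnot(inherits(card, "scorecard"))
  if (!file.exists(pdb_in)) abort(sprintf("PDB file not found: '%s'", pdb_in))
  lines <- readLines(pdb_in, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(is_atom)) abort(sprintf("No ATOM records in '%s'.", pdb_in))

  idx <- which(is_atom)
  recs <- lines[idx]
  resname <- trimws(substr(recs, 18, 20))
  chain <- substr(recs, 22, 22)
  resid <- paste0(chain, ":", substr(recs, 23, 27))  # resseq + icode
  std <- startsWith(lines[idx], "ATOM  ") & resname %in% names(AA_THREE_TO_ONE)

  # residue-level table in order of first appearance
  first_seen <- !duplicated(resid)
  res_tbl <- data.frame(
    resid = resid[first_seen],
    chain = chain[first_seen],
    one = ifelse(std[first_seen], AA_THREE_TO_ONE[resname[first_seen]], NA),
    stringsAsFactors = FALSE
  )
  res_tbl$value <- 0
  for (ch in unique(res_tbl$chain)) {
    rows <- which(res_tbl$chain == ch & !is.na(res_tbl$one))
    if (length(rows) == 0L) next
    seqstr <- paste(res_tbl$one[rows], collapse = "")
    v <- if (source == "dipeptide" && length(rows) >= 2L) {
      track_values(seqstr, card, "dipeptide")
    } else {
      track_values(seqstr, card, "aa")
    }
    res_tbl$value[rows] <- v
  }
  vals <- setNames(res_tbl$value, res_tbl$resid)
  mapped <- setNames(!is.na(res_tbl$one), res_tbl$resid)

  bfac <- ifelse(mapped[resid], vals[resid] / 10, 0)
  pad <- function(x, width) formatC(x, width = width, flag = "-")
  recs <- vapply(seq_along(recs), function(k) {
    ln <- recs[k]
    if (nchar(ln) < 66L) ln <- pad(ln, 66L)
    paste0(substr(ln, 1, 60), sprintf("%6.2f", bfac[k]), substr(ln, 67, nchar(ln)))
  }, character(1))
  lines[idx] <- recs
  out <- c(
    "REMARK 999 B-FACTOR COLUMN REWRITTEN WITH PROPENSITY SCORE / 10 (0-100)",
    lines
  )
  writeLines(out, pdb_out)
  tibble(
    n_atoms = length(idx),
    n_residues = sum(mapped),
    n_unmapped_residues = sum(!mapped),
    n_unmapped_atoms = sum(!mapped[resid])
  )
}
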