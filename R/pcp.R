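# AAindex1 flat-file parsing and correlation mining of amino-acid
# propensity scores against physicochemical property (PCP) scales.

# AAindex1 lists the 20 values in this residue order, ten per data line.
.aaindex_order <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y"
)

#' Parse an AAindex1-format flat file
#'
#' Reads a flat file of amino-acid index records. Each record starts with an
#' accession line `H <accession>`, carries a description on `D` lines, lists
#' its 20 values after the `I` header line (two rows of ten, residue order
#' `A R N D C Q E G H I / L K M F P S T V W Y`) and ends with `//`. The
#' token `NA` marks a missing value; missing values are recorded, not
#' dropped — filtering is the business of [mine_pcps()].
#'
#' @param path Path to an AAindex1 flat file.
#' @return A tibble with one row per record: `accession`, `description`,
#'   `n_na` (number of missing residues) and a list-column `values` holding
#'   the named 20-vector (canonical residue order, NA where missing).
#' @seealso [aaindex_fixture_path()] for the bundled demonstration file.
#' @export
parse_aaindex <- function(path) {
  if (!file.exists(path)) abort(sprintf("AAindex file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "H ")) {
      i <- i + 1L
      next
    }
    acc <- trimws(sub("^H ", "", lines[i]))
    desc <- character(0)
    vals <- character(0)
    in_values <- FALSE
    i <- i + 1L
    while (i <= n && !startsWith(lines[i], "//")) {
      ln <- lines[i]
      key <- substr(ln, 1, 1)
      if (key == "D") {
        desc <- c(desc, trimws(sub("^D ", "", ln)))
        in_values <- FALSE
      } else if (key == "I") {
        in_values <- TRUE
      } else if (in_values && grepl("^\\s", ln)) {
        vals <- c(vals, strsplit(trimws(ln), "\\s+")[[1]])
      } else {
        in_values <- FALSE
      }
      i <- i + 1L
    }
    i <- i + 1L  # skip //
    if (length(vals) != 20L) {
      abort(sprintf(
        "AAindex record '%s' has %d values; expected 20.", acc, length(vals)
      ))
    }
    v <- suppressWarnings(as.numeric(vals))
    bad <- is.na(v) & vals != "NA"
    if (any(bad)) {
      abort(sprintf(
        "AAindex record '%s' has non-numeric value(s): %s",
        acc, paste(vals[bad], collapse = ", ")
      ))
    }
    names(v) <- .aaindex_order
    recs[[length(recs) + 1L]] <- list(
      accession = acc,
      description = paste(desc, collapse = " "),
      values = v[AA_ALPHABET]
    )
  }
  if (length(recs) == 0L) abort(sprintf("No AAindex records found in '%s'.", path))
  acc <- vapply(recs, `[[`, character(1), "accession")
  if (anyDuplicated(acc)) {
    abort(sprintf(
      "Duplicate AAindex accession(s): %s",
      paste(unique(acc[duplicated(acc)]), collapse = ", ")
    ))
  }
  tibble(
    accession = acc,
    description = vapply(recs, `[[`, character(1), "description"),
    n_na = vapply(recs, function(r) sum(is.na(r$values)), integer(1)),
    values = lapply(recs, `[[`, "values")
  )
}

#' Serialise parsed AAindex entries back to the flat-file format
#'
#' @param entries A tibble as returned by [parse_aaindex()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(entries, path) {
  fmt <- function(x) {
    ifelse(is.na(x), "NA", format(x, trim = TRUE, scientific = FALSE, digits = 15))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(entries))) {
    v <- entries$values[[k]][.aaindex_order]
    writeLines(c(
      paste("H", entries$accession[k]),
      paste("D", entries$description[k]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y",
      paste0("    ", paste(fmt(v[1:10]), collapse = "  ")),
      paste0("    ", paste(fmt(v[11:20]), collapse = "  ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' Screen physicochemical scales against amino-acid propensity scores
#'
#' Computes the Pearson correlation between a 20-value amino-acid propensity
#' vector and every parsed scale, keeping scales whose correlation clears a
#' threshold. The default signed mode keeps `r > min_r` (matching the
#' convention of selecting positively correlated candidate properties);
#' absolute mode keeps `|r| > min_r`, since strongly anti-correlated scales
#' are equally informative. Under `na_policy = "drop_entry"` every scale
#' with any missing residue is excluded before correlating (the classical
#' "remove NA-containing indices" filter); `"pairwise_complete"` instead
#' correlates over the residues present in both vectors.
#'
#' @param entries A tibble from [parse_aaindex()].
#' @param aa_scores A named 20-vector of amino-acid scores, or a
#'   `scorecard`.
#' @param min_r Correlation threshold (default 0.5).
#' @param mode `"signed"` or `"absolute"`.
#' @param na_policy `"drop_entry"` or `"pairwise_complete"`.
#' @return A tibble of hits sorted by descending `r` (signed) or `|r|`
#'   (absolute): `accession`, `description`, `r`, `n_used`.
#' @export
mine_pcps <- function(entries, aa_scores, min_r = 0.5,
                      mode = c("signed", "absolute"),
                      na_policy = c("drop_entry", "pairwise_complete")) {
  mode <- match.arg(mode)
  na_policy <- match.arg(na_policy)
  if (inherits(aa_scores, "scorecard")) aa_scores <- aa_scores$aa_scores
  if (length(aa_scores) != 20L || !setequal(names(aa_scores), AA_ALPHABET)) {
    abort("`aa_scores` must be a named vector over the 20 canonical residues.")
  }
  if (!is.data.frame(entries) || nrow(entries) == 0L) {
    abort("`entries` must be a non-empty tibble from parse_aaindex().")
  }
  aa_scores <- aa_scores[AA_ALPHABET]
  keep <- if (na_policy == "drop_entry") {
    vapply(entries$values, function(v) !anyNA(v), logical(1))
  } else {
    rep(TRUE, nrow(entries))
  }
  entries <- entries[keep, , drop = FALSE]
  rs <- vapply(entries$values, function(v) {
    v <- v[AA_ALPHABET]
    ok <- !is.na(v)
    if (sum(ok) < 3L) return(NA_real_)
    pearson_r(aa_scores[ok], v[ok])
  }, numeric(1))
  n_used <- vapply(entries$values, function(v) sum(!is.na(v)), integer(1))
  hits <- tibble(
    accession = entries$accession,
    description = entries$description,
    r = rs,
    n_used = n_used
  )
  hits <- hits[!is.na(hits$r), , drop = FALSE]
  hits <- if (mode == "signed") {
    dplyr::arrange(hits[hits$r > min_r, , drop = FALSE], dplyr::desc(.data$r))
  } else {
    dplyr::arrange(hits[abs(hits$r) > min_r, , drop = FALSE], dplyr::desc(abs(.data$r)))
  }
  hits
}

#' Correlate amino-acid scores with an embedded reference column
#'
#' Pearson correlation (pairwise-complete over non-NA residues) between a
#' 20-value amino-acid score vector and one of the embedded published
#' scales; the hydration-energy column has NA for E, R, D, K and P, so its
#' correlation uses the 15 measured residues.
#'
#' @param aa_scores Named 20-vector or `scorecard`.
#' @param fixture One of `"single_span_aac"`, `"nakh920108"`,
#'   `"wolr810101"`, `"hydration_energy"`, `"kytj820101"`, `"werd780104"`,
#'   `"olsk800101"`.
#' @return The correlation (scalar).
#' @export
correlate_with_table <- function(aa_scores,
                                 fixture = c("single_span_aac", "nakh920108",
                                             "wolr810101", "hydration_energy",
                                             "kytj820101", "werd780104",
                                             "olsk800101")) {
  fixture <- match.arg(fixture)
  if (inherits(aa_scores, "scorecard")) aa_scores <- aa_scores$aa_scores
  map <- c(
    single_span_aac = "table4_single_span",
    nakh920108 = "table4_nakh",
    wolr810101 = "table4_wolr",
    hydration_energy = "table4_hydration",
    kytj820101 = "table3_kytj",
    werd780104 = "table3_werd",
    olsk800101 = "table3_olsk"
  )
  ref <- paper_fixture(map[[fixture]])
  pearson_r(aa_scores[AA_ALPHABET], ref, na_policy = "pairwise_complete")
}

#' Path to the bundled AAindex demonstration file
#'
#' A small AAindex1-format file carrying the physicochemical scales used by
#' the characterization examples (hydropathy index, helix free-energy
#' change, average internal preferences, multi-span helix composition,
#' hydration potential), with values as printed in the embedded reference
#' tables.
#'
#' @return A file path.
#' @export
aaindex_fixture_path <- function() {
  system.file("extdata", "aaindex_scales.txt", package = "scmseq", mustWork = TRUE)
}
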