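# Shared fixtures and independent brute-force oracles. The oracles use only
# plain loops / direct formulas so they stay independent of the package's
# vectorised implementations.

ALPHA <- amino_acids()

rand_seqs <- function(n, lmin = 10, lmax = 40, seed = 1, prefix = "s") {
  withr::with_seed(seed, {
    lens <- lmin + sample.int(lmax - lmin + 1L, n, replace = TRUE) - 1L
    tibble::tibble(
      id = paste0(prefix, seq_len(n)),
      description = "",
      residues = vapply(lens, function(L) {
        paste(sample(ALPHA, L, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

rand_card <- function(seed = 1, threshold = 500) {
  withr::with_seed(seed, {
    dps <- stats::setNames(stats::runif(400, 0, 1000), dipeptides())
    make_scorecard(dps, threshold = threshold)
  })
}

# Brute-force dipeptide counts by explicit window enumeration.
bf_dpc <- function(seq) {
  out <- stats::setNames(numeric(400), dipeptides())
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(length(chars) - 1)) {
    dp <- paste0(chars[i], chars[i + 1])
    out[dp] <- out[dp] + 1
  }
  out / (length(chars) - 1)
}

# Brute-force AUC by pair counting with half-weighted ties.
bf_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Brute-force amino-acid scores by explicit 40-slot enumeration.
bf_aa_scores <- function(dps) {
  vapply(ALPHA, function(x) {
    slots <- c(
      vapply(ALPHA, function(j) dps[[paste0(x, j)]], numeric(1)),
      vapply(ALPHA, function(i) dps[[paste0(i, x)]], numeric(1))
    )
    mean(slots)
  }, numeric(1))
}

# Brute-force sequence score: sum of DPS over windows, divided by L - 1.
bf_score <- function(seq, dps) {
  chars <- strsplit(seq, "")[[1]]
  s <- 0
  for (i in seq_len(length(chars) - 1)) {
    s <- s + dps[[paste0(chars[i], chars[i + 1])]]
  }
  s / (length(chars) - 1)
}

# Exhaustive threshold scan matching the documented candidate set.
bf_threshold <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cand <- c(v[1] - 1, if (length(v) > 1) (utils::head(v, -1) + utils::tail(v, -1)) / 2,
            v[length(v)] + 1)
  best <- NULL
  for (t in cand) {
    tp <- sum(pos > t); tn <- sum(neg <= t)
    acc <- (tp + tn) / (length(pos) + length(neg))
    ss <- tp / length(pos) + tn / length(neg)
    if (is.null(best) || acc > best$acc + 1e-15 ||
        (abs(acc - best$acc) <= 1e-15 && ss > best$ss + 1e-15)) {
      best <- list(t = t, acc = acc, ss = ss)
    }
  }
  best$t
}

# Minimal but column-correct PDB ATOM/HETATM record.
pdb_record <- function(type, serial, atom, resn, chain, resseq,
                       x = 1, y = 2, z = 3, occ = 1, bfac = 25.5, elem = "C") {
  sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    type, serial, atom, resn, chain, resseq, x, y, z, occ, bfac, elem
  )
}

# A two-chain toy structure: chain A = Ile-Gly-Leu (2 atoms each),
# chain B = single Phe, plus a HETATM water.
toy_pdb <- function(path) {
  lines <- c(
    pdb_record("ATOM", 1, "N", "ILE", "A", 1, elem = "N"),
    pdb_record("ATOM", 2, "CA", "ILE", "A", 1),
    pdb_record("ATOM", 3, "N", "GLY", "A", 2, elem = "N"),
    pdb_record("ATOM", 4, "CA", "GLY", "A", 2),
    pdb_record("ATOM", 5, "N", "LEU", "A", 3, elem = "N"),
    pdb_record("ATOM", 6, "CA", "LEU", "A", 3),
    "TER       7      LEU A   3",
    pdb_record("ATOM", 8, "CA", "PHE", "B", 1),
    pdb_record("HETATM", 9, "O", "HOH", "B", 101, elem = "O"),
    "END"
  )
  writeLines(lines, path)
  path
}

write_tmp_fasta <- function(seqs, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = envir)
  write_fasta(seqs, path)
  path
}
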