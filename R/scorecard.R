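# Scorecard object: 400 dipeptide propensity scores in [0, 1000], 20 derived
# amino-acid scores, a decision threshold on the S(P) scale, and a meta block.

new_scorecard <- function(dipeptide_scores, aa_scores, threshold, meta = list()) {
  card <- structure(
    list(
      dipeptide_scores = dipeptide_scores,
      aa_scores = aa_scores,
      threshold = threshold,
      meta = meta
    ),
    class = "scorecard"
  )
  validate_scorecard(card)
}

validate_scorecard <- function(card) {
  dps <- card$dipeptide_scores
  aas <- card$aa_scores
  if (length(dps) != 400L || !setequal(names(dps), DIPEPTIDES)) {
    abort("A scorecard needs exactly the 400 canonical dipeptide scores.")
  }
  if (length(aas) != 20L || !setequal(names(aas), AA_ALPHABET)) {
    abort("A scorecard needs exactly the 20 canonical amino-acid scores.")
  }
  if (anyNA(dps) || anyNA(aas)) abort("Scorecard scores must not be NA.")
  if (any(dps < 0 | dps > 1000) || any(aas < 0 | aas > 1000)) {
    abort("Scorecard scores must lie in [0, 1000].")
  }
  if (!is.numeric(card$threshold) || length(card$threshold) != 1L || is.na(card$threshold)) {
    abort("A scorecard needs a single numeric decision threshold.")
  }
  # keep canonical ordering internally
  card$dipeptide_scores <- dps[DIPEPTIDES]
  card$aa_scores <- aas[AA_ALPHABET]
  card
}

#' Construct a scorecard from explicit scores
#'
#' Builds a `scorecard` object from a full set of dipeptide scores, e.g.
#' published propensities or scores produced outside the training pipeline.
#' Amino-acid scores default to the 40-slot derivation of
#' [derive_aa_scores()] but may be supplied directly (published amino-acid
#' propensities do not always equal the derivation from rounded dipeptide
#' scores).
#'
#' @param dipeptide_scores Named numeric vector over the 400 canonical
#'   dipeptides, values in \[0, 1000\].
#' @param aa_scores Optional named 20-vector; derived from
#'   `dipeptide_scores` when omitted.
#' @param threshold Decision threshold on the sequence-score scale
#'   (default 500, the neutral mid-scale).
#' @param meta Optional provenance list.
#' @return A `scorecard`.
#' @export
make_scorecard <- function(dipeptide_scores, aa_scores = NULL,
                           threshold = 500, meta = list()) {
  if (is.null(aa_scores)) aa_scores <- derive_aa_scores(dipeptide_scores)
  if (is.null(meta$type)) meta$type <- "manual"
  new_scorecard(dipeptide_scores, aa_scores, threshold, meta)
}

#' Build the initial dipeptide propensity scorecard
#'
#' The raw score of each dipeptide is the difference between its mean
#' composition in the positive and negative classes. Raw scores are then
#' min-max rescaled to propensities in \[0, 1000\] with a single global
#' minimum/maximum over all 400 raw scores,
#' `S' = 1000 (S - min) / (max - min)`, so the most positive-class-enriched
#' dipeptide scores exactly 1000 and the most depleted exactly 0.
#' Amino-acid scores are derived with [derive_aa_scores()] and a decision
#' threshold is selected on the training scores with [select_threshold()].
#'
#' If all 400 raw differences are equal (e.g. the two classes are identical)
#' the normalisation is degenerate: every score is set to 500 and a warning
#' is raised.
#'
#' @param pos,neg Sequence tibbles (or character vectors) for the positive
#'   and negative class; both non-empty, all sequences of length >= 2.
#' @param pooling Class-composition pooling, see [mean_class_composition()].
#' @return A `scorecard` object.
#' @seealso [train_scorecard()] for the GA-optimised card.
#' @export
initial_scorecard <- function(pos, neg,
                              pooling = c("mean_of_sequences", "pooled_counts")) {
  pooling <- match.arg(pooling)
  rp <- seq_residues(pos, "pos")
  rn <- seq_residues(neg, "neg")
  raw <- mean_comp_vec(rp, "dipeptide", pooling) -
    mean_comp_vec(rn, "dipeptide", pooling)
  rng <- range(raw)
  if (diff(rng) == 0) {
    warn("All raw dipeptide score differences are equal; setting every propensity to 500.")
    dps <- setNames(rep(500, 400L), DIPEPTIDES)
  } else {
    # ratio before scaling so the extremes hit exactly 0 and 1000 in
    # floating point; clamp guards any residual rounding overshoot
    dps <- ((raw - rng[1]) / (rng[2] - rng[1])) * 1000
    dps <- pmin(pmax(dps, 0), 1000)
  }
  aas <- derive_aa_scores(dps)
  thr <- select_threshold(score_vec(rp, dps), score_vec(rn, dps))
  new_scorecard(dps, aas, thr, meta = list(
    type = "initial",
    n_pos = length(rp), n_neg = length(rn),
    pooling = pooling,
    version = as.character(utils::packageVersion("scmseq"))
  ))
}

#' Derive amino-acid propensity scores from dipeptide scores
#'
#' The score of amino acid X is the mean over the 40-slot multiset of all
#' dipeptide scores containing X: the 20 scores with X first plus the 20
#' with X second, so the homodipeptide XX is counted twice. This symmetric
#' rule makes the mean of the 20 amino-acid scores equal the mean of the 400
#' dipeptide scores exactly.
#'
#' @param dipeptide_scores Named numeric vector over the 400 canonical
#'   dipeptides (a `scorecard` is also accepted).
#' @return Named numeric vector of 20 amino-acid scores.
#' @export
derive_aa_scores <- function(dipeptide_scores) {
  if (inherits(dipeptide_scores, "scorecard")) {
    dipeptide_scores <- dipeptide_scores$dipeptide_scores
  }
  if (length(dipeptide_scores) != 400L || !setequal(names(dipeptide_scores), DIPEPTIDES)) {
    abort("`dipeptide_scores` must cover exactly the 400 canonical dipeptides.")
  }
  m <- matrix(dipeptide_scores[DIPEPTIDES], nrow = 20L, ncol = 20L, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  (rowSums(m) + colSums(m)) / 40
}

# Internal fast path: scores for a residue vector under a dps vector.
# Count-then-divide keeps the weighted sum numerically faithful.
score_vec <- function(residues, dps) {
  cc <- dpc_counts(residues)
  as.vector(cc$counts %*% dps[DIPEPTIDES]) / unname(cc$windows)
}

#' Score sequences with a scorecard
#'
#' The score of a query sequence P is the composition-weighted sum
#' `S(P) = sum_i w_i DPS_i` over the 400 dipeptides, where w is the
#' dipeptide composition of P. Because the weights are non-negative and sum
#' to 1, `S(P)` always lies between the smallest and largest dipeptide score
#' of the card.
#'
#' @param seqs Sequence tibble or character vector (lengths >= 2).
#' @param card A `scorecard`.
#' @return A tibble with columns `id` and `score`.
#' @export
score_sequences <- function(seqs, card) {
  stopifnot(inherits(card, "scorecard"))
  res <- seq_residues(seqs)
  tibble(id = names(res), score = score_vec(res, card$dipeptide_scores))
}

#' Classify sequences with a trained scorecard
#'
#' A sequence is called positive iff its score is strictly greater than the
#' card's threshold; ties are classed negative.
#'
#' @inheritParams score_sequences
#' @return A tibble with columns `id`, `score`, `label`
#'   (`"positive"`/`"negative"`).
#' @export
classify_sequences <- function(seqs, card) {
  score_sequences(seqs, card) |>
    dplyr::mutate(label = ifelse(.data$score > card$threshold, "positive", "negative"))
}

#' Select the decision threshold maximising training accuracy
#'
#' Candidate thresholds are the midpoints between adjacent distinct values
#' of the pooled sorted scores, plus one sentinel below the minimum and one
#' above the maximum. Accuracy uses the strict rule (positive iff
#' score > threshold). Ties in accuracy are broken by the larger
#' sensitivity + specificity, then by the smallest candidate.
#'
#' @param scores_pos,scores_neg Numeric score vectors for the two classes.
#' @return The selected threshold (scalar).
#' @export
select_threshold <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    abort("Both score vectors must be non-empty.")
  }
  v <- sort(unique(c(scores_pos, scores_neg)))
  cand <- c(v[1] - 1, if (length(v) > 1L) (head(v, -1L) + tail(v, -1L)) / 2, v[length(v)] + 1)
  n <- length(scores_pos)
  m <- length(scores_neg)
  tp <- vapply(cand, function(t) sum(scores_pos > t), numeric(1))
  tn <- vapply(cand, function(t) sum(scores_neg <= t), numeric(1))
  acc <- (tp + tn) / (n + m)
  ss <- tp / n + tn / m
  best <- which(acc == max(acc))
  best <- best[ss[best] == max(ss[best])]
  cand[min(best)]
}

#' Save or load a scorecard as JSON
#'
#' The JSON schema has keys `dipeptide_scores` (object keyed by two-letter
#' dipeptide), `aa_scores` (object keyed by residue), `threshold` (number)
#' and `meta` (object). Numbers are serialised at full precision so a
#' save/load round trip is bit-exact on all scores. Loading validates the
#' schema and score ranges and fails naming the missing key otherwise.
#'
#' @param card A `scorecard`.
#' @param path File path for the JSON.
#' @return `save_scorecard()` returns `path` invisibly; `load_scorecard()`
#'   returns the `scorecard`.
#' @export
save_scorecard <- function(card, path) {
  card <- validate_scorecard(card)
  jsonlite::write_json(
    list(
      dipeptide_scores = as.list(card$dipeptide_scores),
      aa_scores = as.list(card$aa_scores),
      threshold = card$threshold,
      meta = card$meta
    ),
    path,
    # 17 significant digits round-trip IEEE doubles exactly
    auto_unbox = TRUE, digits = I(17), pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname save_scorecard
#' @export
load_scorecard <- function(path) {
  if (!file.exists(path)) abort(sprintf("Scorecard file not found: '%s'", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("dipeptide_scores", "aa_scores", "threshold")) {
    if (is.null(x[[key]])) abort(sprintf("Scorecard JSON is missing key '%s'.", key))
  }
  new_scorecard(
    unlist(x$dipeptide_scores),
    unlist(x$aa_scores),
    x$threshold,
    meta = if (is.null(x$meta)) list() else x$meta
  )
}

#' @export
print.scorecard <- function(x, ...) {
  dps <- x$dipeptide_scores
  cat("<scorecard>\n")
  cat(sprintf("  dipeptide scores: 400, range %.1f-%.1f\n", min(dps), max(dps)))
  top <- names(sort(dps, decreasing = TRUE))[1:5]
  bot <- names(sort(dps))[1:5]
  cat(sprintf("  top dipeptides:    %s\n", paste(top, collapse = " ")))
  cat(sprintf("  bottom dipeptides: %s\n", paste(bot, collapse = " ")))
  cat(sprintf("  threshold: %.2f\n", x$threshold))
  if (!is.null(x$meta$type)) cat(sprintf("  type: %s\n", x$meta$type))
  invisible(x)
}

#' Tidy a scorecard into a dipeptide score table
#'
#' @param x A `scorecard`.
#' @param ... Unused.
#' @return A tibble with columns `dipeptide`, `first`, `second`, `score`,
#'   one row per dipeptide in canonical order.
#' @export
tidy.scorecard <- function(x, ...) {
  tibble(
    dipeptide = DIPEPTIDES,
    first = substr(DIPEPTIDES, 1, 1),
    second = substr(DIPEPTIDES, 2, 2),
    score = unname(x$dipeptide_scores[DIPEPTIDES])
  )
}

#' One-row summary of a scorecard
#'
#' @param x A `scorecard`.
#' @param ... Unused.
#' @return A one-row tibble with the threshold, score-range summary and, if
#'   present in the meta block, the achieved fitness/AUC/R of training.
#' @export
glance.scorecard <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    min_score = min(x$dipeptide_scores),
    max_score = max(x$dipeptide_scores),
    mean_score = mean(x$dipeptide_scores),
    fitness = x$meta$fitness %||% NA_real_,
    auc = x$meta$auc %||% NA_real_,
    r = x$meta$r %||% NA_real_
  )
}
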