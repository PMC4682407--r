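# Performance metrics, stratified cross-validation and the Mann-Whitney
# comparison of class dipeptide compositions.

mcc_from_counts <- function(tp, tn, fp, fn) {
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Evaluate a scorecard on a labelled sequence set
#'
#' Classifies every sequence with [classify_sequences()] and reports the
#' confusion counts together with accuracy, sensitivity, specificity, the
#' Matthews correlation coefficient (defined 0 when any marginal is 0) and
#' the rank-based AUC of the raw scores.
#'
#' @param pos,neg Sequence tibbles or character vectors for the positive
#'   and negative class.
#' @param card A trained `scorecard`.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `mcc`, `auc`.
#' @export
evaluate_scorecard <- function(pos, neg, card) {
  stopifnot(inherits(card, "scorecard"))
  sp <- score_sequences(pos, card)$score
  sn <- score_sequences(neg, card)$score
  tp <- sum(sp > card$threshold)
  fn <- length(sp) - tp
  tn <- sum(sn <= card$threshold)
  fp <- length(sn) - tn
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    mcc = mcc_from_counts(tp, tn, fp, fn),
    auc = auc_rank(sp, sn)
  )
}

#' Stratified k-fold cross-validation of the full training protocol
#'
#' Each class is shuffled with the configuration seed and split into `k`
#' parts whose sizes differ by at most 1. For every fold, a scorecard is
#' trained on the remaining k-1 parts with [train_scorecard()] and evaluated
#' on the held-out part. Inside folds the number of GA restarts defaults to
#' 1 (`runs_per_fold`) to keep cross-validation desk-scale; the outer
#' multi-restart protocol is reserved for the final model.
#'
#' @param pos,neg Sequence tibbles or character vectors; each class must
#'   have at least `k` members.
#' @param config A [ga_config()]; its seed drives both fold assignment and
#'   per-fold training.
#' @param k Number of folds (>= 2, default 10).
#' @param runs_per_fold GA restarts per fold (default 1).
#' @return An `scm_cv` object; `tidy()` returns the per-fold metric table
#'   and `glance()` the unweighted mean across folds.
#' @export
cross_validate <- function(pos, neg, config = ga_config(), k = 10L,
                           runs_per_fold = 1L) {
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2.")
  rp <- seq_residues(pos, "pos")
  rn <- seq_residues(neg, "neg")
  if (length(rp) < k || length(rn) < k) {
    abort("Each class must have at least `k` sequences.")
  }
  folds <- with_seed(config$seed, list(
    pos = sample(rep_len(seq_len(k), length(rp))),
    neg = sample(rep_len(seq_len(k), length(rn)))
  ))
  cfg <- config
  cfg$runs <- as.integer(runs_per_fold)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    card <- train_scorecard(rp[folds$pos != f], rn[folds$neg != f], cfg)
    reports[[f]] <- dplyr::bind_cols(
      tibble(fold = f),
      evaluate_scorecard(rp[folds$pos == f], rn[folds$neg == f], card)
    )
  }
  folds_tbl <- dplyr::bind_rows(reports)
  structure(
    list(
      folds = folds_tbl,
      mean = dplyr::summarise(
        folds_tbl,
        dplyr::across(c("accuracy", "sensitivity", "specificity", "mcc", "auc"), mean)
      ),
      assignment = folds,
      k = k
    ),
    class = "scm_cv"
  )
}

#' @export
print.scm_cv <- function(x, ...) {
  cat(sprintf("<scm_cv> %d-fold stratified cross-validation\n", x$k))
  cat(sprintf(
    "  mean accuracy %.4f, sensitivity %.4f, specificity %.4f, MCC %.4f, AUC %.4f\n",
    x$mean$accuracy, x$mean$sensitivity, x$mean$specificity, x$mean$mcc, x$mean$auc
  ))
  invisible(x)
}

#' @rdname cross_validate
#' @param x An `scm_cv` object.
#' @param ... Unused.
#' @export
tidy.scm_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @export
glance.scm_cv <- function(x, ...) x$mean

#' Mann-Whitney comparison of class dipeptide compositions
#'
#' For each of the 400 dipeptides, compares the per-sequence composition
#' values of the two classes with the two-sided Mann-Whitney U test
#' (midranks for ties). The exact null distribution is enumerated when
#' `n * m <= 400` and the samples are tie-free; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' A Benjamini-Hochberg adjusted column (`p_bh`) is included alongside the
#' raw p-values as a modern extension; no correction is applied to `p_value`
#' itself.
#'
#' @param pos,neg Sequence tibbles or character vectors; each class needs
#'   at least 2 sequences.
#' @return A tibble sorted by `p_value` with columns `dipeptide`,
#'   `mean_pos`, `mean_neg`, `statistic` (U for the positive class) and
#'   `p_value`, `p_bh`.
#' @export
dipeptide_utest <- function(pos, neg) {
  rp <- seq_residues(pos, "pos")
  rn <- seq_residues(neg, "neg")
  if (length(rp) < 2L || length(rn) < 2L) {
    abort("Each class needs at least 2 sequences.")
  }
  Xp <- dpc_matrix(rp)
  Xn <- dpc_matrix(rn)
  n <- nrow(Xp)
  m <- nrow(Xn)
  res <- lapply(seq_len(400L), function(j) {
    x <- Xp[, j]
    y <- Xn[, j]
    exact <- (n * m <= 400L) && !anyDuplicated(c(x, y))
    if (length(unique(c(x, y))) == 1L) {
      # fully tied samples: no evidence of difference
      p <- 1
    } else {
      p <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
      )
    }
    u <- sum(rank(c(x, y))[seq_len(n)]) - n * (n + 1) / 2
    c(mean_pos = mean(x), mean_neg = mean(y), statistic = u, p_value = min(p, 1))
  })
  out <- as_tibble(do.call(rbind, res))
  out$dipeptide <- DIPEPTIDES
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(
    out[, c("dipeptide", "mean_pos", "mean_neg", "statistic", "p_value", "p_bh")],
    .data$p_value
  )
}
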