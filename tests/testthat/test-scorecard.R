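test_that("initial scorecard maps extreme class differences to 0 and 1000", {
  pos <- rep("LFLFLFLFLF", 10)
  neg <- rep("QNQNQNQNQN", 10)
  card <- initial_scorecard(pos, neg)
  expect_equal(card$dipeptide_scores[["LF"]], 1000)
  expect_equal(card$dipeptide_scores[["QN"]], 0)
})

test_that("identical classes hit the degenerate path with all scores 500", {
  seqs <- rand_seqs(5, seed = 2)
  expect_warning(card <- initial_scorecard(seqs, seqs), "500")
  expect_true(all(card$dipeptide_scores == 500))
  expect_true(all(card$aa_scores == 500))
})

test_that("initial scores equal a brute-force difference plus min-max rescale", {
  pos <- rand_seqs(6, seed = 11)
  neg <- rand_seqs(6, seed = 12)
  card <- initial_scorecard(pos, neg)
  raw <- Reduce(`+`, lapply(pos$residues, bf_dpc)) / 6 -
    Reduce(`+`, lapply(neg$residues, bf_dpc)) / 6
  want <- 1000 * (raw - min(raw)) / (max(raw) - min(raw))
  expect_equal(card$dipeptide_scores, want, tolerance = 1e-12)
  # normalisation attains the range ends at the extreme dipeptides
  expect_equal(min(card$dipeptide_scores), 0)
  expect_equal(max(card$dipeptide_scores), 1000)
})

test_that("amino-acid derivation follows the 40-slot multiset rule", {
  const <- make_scorecard(stats::setNames(rep(250, 400), dipeptides()))
  expect_true(all(const$aa_scores == 250))

  dps <- stats::setNames(rep(0, 400), dipeptides())
  dps[startsWith(names(dps), "A")] <- 1000
  aa <- derive_aa_scores(dps)
  expect_equal(aa[["A"]], 525)  # (20 * 1000 + 1000) / 40, AA counted twice
  expect_equal(unname(aa[names(aa) != "A"]), rep(25, 19))

  card <- rand_card(7)
  expect_equal(card$aa_scores, bf_aa_scores(card$dipeptide_scores))
})

test_that("sequence scores are composition-weighted sums bounded by the card", {
  uniform <- make_scorecard(stats::setNames(rep(500, 400), dipeptides()))
  seqs <- rand_seqs(5, seed = 4)
  expect_equal(score_sequences(seqs, uniform)$score, rep(500, 5))

  lf <- stats::setNames(rep(0, 400), dipeptides())
  lf[["LF"]] <- 1000
  expect_equal(
    score_sequences(c(x = "LFLF"), make_scorecard(lf))$score,
    2000 / 3
  )

  card <- rand_card(9)
  seqs30 <- rand_seqs(4, lmin = 30, lmax = 30, seed = 5)
  got <- score_sequences(seqs30, card)$score
  want <- vapply(seqs30$residues, bf_score, numeric(1), dps = card$dipeptide_scores)
  expect_equal(got, unname(want))
  expect_true(all(got >= min(card$dipeptide_scores) & got <= max(card$dipeptide_scores)))

  # invariant to record order and descriptions
  shuffled <- seqs30[c(3, 1, 4, 2), ]
  shuffled$description <- "irrelevant"
  expect_equal(
    score_sequences(shuffled, card)$score,
    got[c(3, 1, 4, 2)]
  )
})

test_that("classification is strict at the threshold", {
  card <- make_scorecard(stats::setNames(rep(500, 400), dipeptides()),
                         threshold = 476.88)
  expect_equal(classify_sequences(c(x = "MKVL"), card)$label, "positive")
  card_tie <- make_scorecard(stats::setNames(rep(500, 400), dipeptides()),
                             threshold = 500)
  expect_equal(classify_sequences(c(x = "MKVL"), card_tie)$label, "negative")
  zero <- make_scorecard(stats::setNames(rep(0, 400), dipeptides()), threshold = 0)
  expect_equal(classify_sequences(c(x = "MKVL"), zero)$label, "negative")
})

test_that("threshold selection maximises accuracy with the documented tie-breaks", {
  expect_equal(select_threshold(c(600, 700), c(400, 500)), 550)
  expect_equal(select_threshold(500, 500), 499)  # sentinel below the value
  pos <- c(1, 3, 5, 7)
  neg <- c(2, 4, 6, 8)
  expect_equal(select_threshold(pos, neg), bf_threshold(pos, neg))
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- round(stats::runif(7, 0, 10), 1)
      q <- round(stats::runif(5, 0, 10), 1)
    })
    expect_equal(select_threshold(p, q), bf_threshold(p, q))
  }
})

test_that("scorecard JSON round-trips bit-exactly and validates its schema", {
  card <- rand_card(13, threshold = 476.88)
  card$meta$note <- "round trip"
  path <- withr::local_tempfile(fileext = ".json")
  save_scorecard(card, path)
  back <- load_scorecard(path)
  expect_identical(back$dipeptide_scores, card$dipeptide_scores)
  expect_identical(back$aa_scores, card$aa_scores)
  expect_identical(back$threshold, card$threshold)

  x <- jsonlite::read_json(path)
  x$threshold <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(x, path2, auto_unbox = TRUE)
  expect_error(load_scorecard(path2), "threshold")

  bad <- card
  bad$dipeptide_scores <- bad$dipeptide_scores[-1]
  expect_error(save_scorecard(bad, path), "400")
  oob <- card
  oob$dipeptide_scores[["AA"]] <- 1001
  expect_error(save_scorecard(oob, path), "0, 1000")
})

test_that("tidy and glance expose the card as tables", {
  card <- rand_card(3, threshold = 321)
  td <- tidy(card)
  expect_equal(nrow(td), 400)
  expect_equal(td$score, unname(card$dipeptide_scores))
  expect_equal(paste0(td$first, td$second), td$dipeptide)
  gl <- glance(card)
  expect_equal(gl$threshold, 321)
  expect_equal(gl$mean_score, mean(card$dipeptide_scores))
})
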