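test_that("rank-based AUC matches brute-force pair counting", {
  expect_equal(auc_rank(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_rank(1, 1), 0.5)
  expect_equal(auc_rank(c(3, 1), c(2, 0)), 0.75)
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(1:30, 1)
      m <- sample(1:30, 1)
      pos <- sample(1:10, n, replace = TRUE)  # ties likely
      neg <- sample(1:10, m, replace = TRUE)
    })
    expect_equal(auc_rank(pos, neg), bf_auc(pos, neg))
  }
  expect_error(auc_rank(numeric(0), 1), "non-empty")
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(99, {
    pos <- stats::rnorm(40, 1)
    neg <- stats::rnorm(60)
  })
  roc <- suppressMessages(pROC::roc(
    response = rep(c(1, 0), c(40, 60)),
    predictor = c(pos, neg),
    direction = "<", quiet = TRUE
  ))
  expect_equal(auc_rank(pos, neg), as.numeric(pROC::auc(roc)))
})

test_that("pearson_r implements the product-moment formula with NA policies", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_r(1:4, c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_r(1:5, -(1:5) * 2 + 3), -1)
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, 1, 3, 5, 4)
  expect_error(pearson_r(x, y), "Missing")
  expect_equal(
    pearson_r(x, y, "pairwise_complete"),
    stats::cor(x[-3], y[-3])
  )
  # symmetry
  withr::with_seed(5, {
    a <- stats::runif(10)
    b <- stats::runif(10)
  })
  expect_equal(pearson_r(a, b), pearson_r(b, a))
  expect_error(pearson_r(c(1, 1, 1), 1:3), "variance")
  expect_error(pearson_r(c(1, NA), c(2, 3), "pairwise_complete"), "3 complete")
})

test_that("fitness combines AUC and amino-acid score conservation", {
  sets <- generate_sequences(synth_config(n_pos = 15, n_neg = 15, seed = 3))
  card <- initial_scorecard(sets$pos, sets$neg)
  cfg <- ga_config()
  f <- scm_fitness(card$dipeptide_scores, card$aa_scores, sets$pos, sets$neg, cfg)
  expect_equal(f$r, 1)  # self-correlation of the initial card
  expect_equal(f$fitness, 0.9 * f$auc + 0.1)

  # random candidate matches the composed independent oracles
  cand <- rand_card(21)$dipeptide_scores
  f2 <- scm_fitness(cand, card$aa_scores, sets$pos, sets$neg, cfg)
  auc_bf <- bf_auc(
    vapply(sets$pos$residues, bf_score, numeric(1), dps = cand),
    vapply(sets$neg$residues, bf_score, numeric(1), dps = cand)
  )
  r_bf <- stats::cor(card$aa_scores, bf_aa_scores(cand))
  expect_equal(f2$auc, auc_bf)
  expect_equal(f2$r, r_bf)
  expect_equal(f2$fitness, 0.9 * auc_bf + 0.1 * r_bf, tolerance = 1e-12)
})

test_that("orthogonal-array crossover honours its contract", {
  a <- rand_card(31)$dipeptide_scores
  b <- rand_card(32)$dipeptide_scores
  fit_const <- function(dps) 1
  expect_equal(oa_crossover(a, a, fit_const, 8), a)

  # fitness = number of genes taken from parent a, 2 factors: the main
  # effects recover parent a exactly (checked against all 4 combinations)
  fit_from_a <- function(dps) sum(dps == a)
  expect_equal(oa_crossover(a, b, fit_from_a, 2), a)

  # with an adversarial fitness preferring parent b
  fit_from_b <- function(dps) sum(dps == b)
  expect_equal(oa_crossover(a, b, fit_from_b, 4), b)

  expect_error(oa_crossover(a, b, fit_const, 1), "at least 2")

  # segment partition: contiguous, covers 1:400, sizes differ by <= 1
  for (k in c(2, 3, 7, 8, 13)) {
    segs <- scmseq:::segment_bounds(k)
    expect_equal(sort(unlist(segs)), 1:400)
    expect_lte(diff(range(lengths(segs))), 1)
  }
  # the orthogonal array is balanced with enough rows
  for (k in c(2, 3, 8, 15)) {
    oa <- scmseq:::oa_table(k)
    expect_gte(nrow(oa), k + 1)
    expect_true(all(colSums(oa == 1) == nrow(oa) / 2))
  }
})

test_that("optimize honours the no-op, elitism and conservation contracts", {
  sets <- generate_sequences(synth_config(n_pos = 20, n_neg = 20, seed = 5))
  card <- initial_scorecard(sets$pos, sets$neg)

  noop <- optimize_scorecard(card, sets$pos, sets$neg,
                             ga_config(generations = 0, seed = 1))
  expect_identical(noop$dipeptide_scores, card$dipeptide_scores)

  cfg <- ga_config(population_size = 12, generations = 8, runs = 1, seed = 2,
                   early_stop = 0)
  opt <- optimize_scorecard(card, sets$pos, sets$neg, cfg)
  expect_true(all(diff(opt$meta$trace) >= 0))  # elitist best-ever trace
  expect_true(all(opt$dipeptide_scores >= 0 & opt$dipeptide_scores <= 1000))
  expect_equal(opt$aa_scores, derive_aa_scores(opt$dipeptide_scores))

  # pure conservation fitness: the initial card is a global optimum
  cons <- optimize_scorecard(card, sets$pos, sets$neg,
                             ga_config(population_size = 8, generations = 4,
                                       runs = 1, seed = 3, w_auc = 0, w_r = 1))
  expect_equal(cons$meta$fitness, 1.0)
})

test_that("multi-run training is reproducible and selects the best run", {
  sets <- generate_sequences(synth_config(n_pos = 20, n_neg = 20, seed = 6))
  cfg1 <- ga_config(population_size = 8, generations = 4, runs = 1, seed = 11)
  single <- train_scorecard(sets$pos, sets$neg, cfg1)
  direct <- optimize_scorecard(initial_scorecard(sets$pos, sets$neg),
                               sets$pos, sets$neg, cfg1)
  expect_identical(single$dipeptide_scores, direct$dipeptide_scores)

  cfg3 <- ga_config(population_size = 8, generations = 4, runs = 3, seed = 11)
  a <- train_scorecard(sets$pos, sets$neg, cfg3)
  b <- train_scorecard(sets$pos, sets$neg, cfg3)
  expect_identical(a$dipeptide_scores, b$dipeptide_scores)
  expect_identical(a$threshold, b$threshold)

  summ <- a$meta$runs_summary
  expect_equal(nrow(summ), 3)
  expect_equal(summ$seed, 11:13)
  sel_acc <- evaluate_scorecard(sets$pos, sets$neg, a)$accuracy
  expect_equal(sel_acc, max(summ$accuracy))
})
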