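# Intelligent genetic algorithm over the 400 dipeptide scores.
# Fitness = w_auc * AUC + w_r * R, where AUC is the rank-based area under
# the ROC curve of the training scores and R is the Pearson correlation
# between the initial and candidate amino-acid propensity vectors.

#' Genetic algorithm configuration
#'
#' Collects the tunable parameters of the intelligent genetic algorithm.
#' Scores are in propensity units on \[0, 1000\].
#'
#' @param population_size Number of chromosomes (default 50).
#' @param generations Generational iterations (default 100); 0 disables
#'   optimisation.
#' @param crossover_rate Probability that a new chromosome is produced by
#'   orthogonal-array crossover rather than copied (default 0.8).
#' @param mutation_rate Per-gene mutation probability (default 0.01).
#' @param mutation_step Mutation half-width: a mutated gene moves by
#'   uniform(-step, step) score units and is clipped to \[0, 1000\]
#'   (default 50).
#' @param oa_factors Number of contiguous chromosome segments treated as
#'   orthogonal-array factors (default 8, >= 2, <= 400).
#' @param elitism Chromosomes carried over unchanged each generation
#'   (default 2).
#' @param seed Integer RNG seed for the run.
#' @param w_auc,w_r Fitness weights for AUC and the amino-acid score
#'   correlation (defaults 0.9 and 0.1; both >= 0).
#' @param runs Independent restarts for [train_scorecard()] (default 10).
#' @param early_stop Stop after this many generations without improvement of
#'   the best-ever fitness (default 20; 0 disables early stopping).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50L,
                      generations = 100L,
                      crossover_rate = 0.8,
                      mutation_rate = 0.01,
                      mutation_step = 50,
                      oa_factors = 8L,
                      elitism = 2L,
                      seed = 1L,
                      w_auc = 0.9,
                      w_r = 0.1,
                      runs = 10L,
                      early_stop = 20L) {
  cfg <- list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    crossover_rate = crossover_rate,
    mutation_rate = mutation_rate,
    mutation_step = mutation_step,
    oa_factors = as.integer(oa_factors),
    elitism = as.integer(elitism),
    seed = as.integer(seed),
    w_auc = w_auc,
    w_r = w_r,
    runs = as.integer(runs),
    early_stop = as.integer(early_stop)
  )
  stopifnot(
    cfg$population_size >= 1L, cfg$generations >= 0L,
    cfg$crossover_rate >= 0, cfg$crossover_rate <= 1,
    cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
    cfg$mutation_step > 0,
    cfg$oa_factors >= 2L, cfg$oa_factors <= 400L,
    cfg$elitism >= 1L, cfg$elitism <= cfg$population_size,
    cfg$w_auc >= 0, cfg$w_r >= 0,
    cfg$runs >= 1L, cfg$early_stop >= 0L
  )
  structure(cfg, class = "ga_config")
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counted 1/2 — equivalently the area under the
#' ROC curve, computed from midranks.
#'
#' @param scores_pos,scores_neg Non-empty numeric score vectors.
#' @return A value in \[0, 1\].
#' @export
auc_rank <- function(scores_pos, scores_neg) {
  n <- length(scores_pos)
  m <- length(scores_neg)
  if (n == 0L || m == 0L) abort("Both score vectors must be non-empty.")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Pearson correlation with explicit missing-value policy
#'
#' Standard product-moment correlation. Under `"pairwise_complete"`,
#' positions where either vector is NA are dropped before computing; under
#' `"error"` any NA is an error. At least 3 complete pairs and non-zero
#' variance in both vectors are required.
#'
#' @param x,y Equal-length numeric vectors.
#' @param na_policy `"error"` or `"pairwise_complete"`.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y, na_policy = c("error", "pairwise_complete")) {
  na_policy <- match.arg(na_policy)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- !(is.na(x) | is.na(y))
  if (na_policy == "error" && !all(ok)) abort("Missing values not allowed under na_policy = 'error'.")
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) abort("Fewer than 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("Zero variance in `x` or `y`.")
  cor(x, y)
}

#' Fitness of a candidate dipeptide score vector
#'
#' `fitness = w_auc * AUC + w_r * R`, where AUC is the rank-based AUC of the
#' training-set scores under the candidate and R is the Pearson correlation
#' between `initial_aa` and the amino-acid scores derived from the
#' candidate. The R term conserves the compositional information of the
#' initial card while AUC drives discrimination.
#'
#' @param candidate Named numeric vector of 400 dipeptide scores.
#' @param initial_aa Named numeric vector of the initial 20 amino-acid
#'   scores.
#' @param pos,neg Training sequence tibbles or character vectors.
#' @param config A [ga_config()].
#' @return A one-row tibble with columns `fitness`, `auc`, `r`.
#' @export
scm_fitness <- function(candidate, initial_aa, pos, neg, config = ga_config()) {
  cp <- dpc_counts(seq_residues(pos, "pos"))
  cn <- dpc_counts(seq_residues(neg, "neg"))
  f <- fitness_eval(candidate[DIPEPTIDES], initial_aa[AA_ALPHABET], cp, cn,
                    config$w_auc, config$w_r)
  tibble(fitness = f$fitness, auc = f$auc, r = f$r)
}

# Internal fitness on precomputed dipeptide count matrices.
fitness_eval <- function(dps, initial_aa, cp, cn, w_auc, w_r) {
  a <- auc_rank(as.vector(cp$counts %*% dps) / cp$windows,
                as.vector(cn$counts %*% dps) / cn$windows)
  r <- cor(initial_aa, derive_aa_scores_fast(dps))
  if (is.na(r)) r <- 0  # degenerate candidate with zero aa-score variance
  list(fitness = w_auc * a + w_r * r, auc = a, r = r)
}

# derive_aa_scores without name validation (hot path).
derive_aa_scores_fast <- function(dps) {
  m <- matrix(dps, nrow = 20L, ncol = 20L, byrow = TRUE)
  (rowSums(m) + colSums(m)) / 40
}

# Two-level orthogonal array with `rows` = smallest power of two such that
# rows - 1 >= factors; built by the Sylvester/Hadamard recursion. Returns a
# rows x factors matrix of levels 1/2.
oa_table <- function(factors) {
  stopifnot(factors >= 2L)
  rows <- 2L
  while (rows - 1L < factors) rows <- rows * 2L
  h <- matrix(1, 1, 1)
  while (nrow(h) < rows) {
    h <- rbind(cbind(h, h), cbind(h, -h))
  }
  lv <- ifelse(h[, 2:(factors + 1L), drop = FALSE] > 0, 1L, 2L)
  matrix(lv, nrow = rows, ncol = factors)
}

# Contiguous partition of 1:400 into `k` segments with sizes differing <= 1.
segment_bounds <- function(k) {
  cuts <- round(seq(0, 400, length.out = k + 1L))
  lapply(seq_len(k), function(i) (cuts[i] + 1L):cuts[i + 1L])
}

#' Orthogonal-array crossover
#'
#' Partitions the 400 genes into `oa_factors` contiguous segments (sizes
#' differing by at most 1, canonical dipeptide order) and uses a two-level
#' orthogonal array to prescribe which parent each segment is taken from in
#' a small set of trial chromosomes. Every array row is evaluated with
#' `fitness_fn`; per-factor main effects (mean fitness at each level) pick
#' the better-sourced segment for a predicted chromosome. The better of the
#' best evaluated row and the predicted chromosome is returned. The child's
#' fitness is not guaranteed to exceed the worse parent's; only this
#' construction is.
#'
#' @param parent_a,parent_b Named numeric vectors of 400 dipeptide scores.
#' @param fitness_fn Function taking a 400-vector and returning a scalar
#'   fitness.
#' @param oa_factors Number of segments (>= 2).
#' @return A named numeric vector of 400 dipeptide scores.
#' @export
oa_crossover <- function(parent_a, parent_b, fitness_fn, oa_factors = 8L) {
  stopifnot(length(parent_a) == 400L, length(parent_b) == 400L)
  oa_factors <- as.integer(oa_factors)
  if (oa_factors < 2L) abort("`oa_factors` must be at least 2.")
  oa <- oa_table(oa_factors)
  segs <- segment_bounds(oa_factors)
  build <- function(levels) {
    child <- parent_a
    for (f in seq_len(oa_factors)) {
      if (levels[f] == 2L) child[segs[[f]]] <- parent_b[segs[[f]]]
    }
    child
  }
  fits <- numeric(nrow(oa))
  for (i in seq_len(nrow(oa))) fits[i] <- fitness_fn(build(oa[i, ]))
  # main effect of each factor: mean fitness at level 1 vs level 2
  pred_levels <- vapply(seq_len(oa_factors), function(f) {
    if (mean(fits[oa[, f] == 1L]) >= mean(fits[oa[, f] == 2L])) 1L else 2L
  }, integer(1))
  predicted <- build(pred_levels)
  best_row <- which.max(fits)
  if (fitness_fn(predicted) >= fits[best_row]) predicted else build(oa[best_row, ])
}

# Per-gene uniform mutation, clipped to [0, 1000]. Consumes RNG: one
# runif(400) gate plus one runif per mutated gene.
mutate_genes <- function(dps, rate, step) {
  hit <- stats::runif(400L) < rate
  if (any(hit)) {
    dps[hit] <- pmin(1000, pmax(0, dps[hit] + stats::runif(sum(hit), -step, step)))
  }
  dps
}

#' Optimise a scorecard with the intelligent genetic algorithm
#'
#' Runs a seeded, reproducible elitist GA over the 400 dipeptide scores.
#' The population is initialised as the initial card plus
#' `population_size - 1` mutated copies. Each generation carries over the
#' `elitism` best chromosomes, then fills the population by tournament
#' selection (size 2), orthogonal-array crossover with probability
#' `crossover_rate` (otherwise the first parent is copied) and per-gene
#' uniform mutation, with all scores clipped to \[0, 1000\]. The best-ever
#' chromosome is returned as a scorecard with amino-acid scores re-derived
#' and the threshold re-selected on the training scores. With
#' `generations = 0` the initial dipeptide scores are returned unchanged
#' (threshold refreshed).
#'
#' The meta block records the configuration, the best fitness/AUC/R and the
#' per-generation best-fitness trace (non-decreasing by elitism).
#'
#' @param initial A `scorecard`, typically from [initial_scorecard()].
#' @param pos,neg Training sequence tibbles or character vectors.
#' @param config A [ga_config()].
#' @param trace_file Optional path; if given, one log line per generation
#'   (generation, best fitness, AUC, R) is appended.
#' @return An optimised `scorecard`.
#' @export
optimize_scorecard <- function(initial, pos, neg, config = ga_config(),
                               trace_file = NULL) {
  stopifnot(inherits(initial, "scorecard"), inherits(config, "ga_config"))
  rp <- seq_residues(pos, "pos")
  rn <- seq_residues(neg, "neg")
  cp <- dpc_counts(rp)
  cn <- dpc_counts(rn)
  initial_aa <- initial$aa_scores[AA_ALPHABET]
  dps0 <- initial$dipeptide_scores[DIPEPTIDES]
  fit1 <- function(dps) {
    fitness_eval(dps, initial_aa, cp, cn, config$w_auc, config$w_r)$fitness
  }

  finish <- function(dps, trace) {
    f <- fitness_eval(dps, initial_aa, cp, cn, config$w_auc, config$w_r)
    thr <- select_threshold(as.vector(cp$counts %*% dps) / cp$windows,
                            as.vector(cn$counts %*% dps) / cn$windows)
    new_scorecard(
      setNames(dps, DIPEPTIDES), derive_aa_scores(setNames(dps, DIPEPTIDES)), thr,
      meta = list(
        type = "optimized",
        n_pos = length(rp), n_neg = length(rn),
        config = unclass(config),
        fitness = f$fitness, auc = f$auc, r = f$r,
        trace = trace,
        version = as.character(utils::packageVersion("scmseq"))
      )
    )
  }

  if (config$generations == 0L) {
    return(finish(dps0, numeric(0)))
  }

  with_seed(config$seed, {
    np <- config$population_size
    pop <- vector("list", np)
    pop[[1]] <- dps0
    for (i in seq_len(np)[-1]) {
      pop[[i]] <- mutate_genes(dps0, config$mutation_rate, config$mutation_step)
    }
    fits <- vapply(pop, fit1, numeric(1))
    best_dps <- pop[[which.max(fits)]]
    best_fit <- max(fits)
    trace <- numeric(config$generations)
    stall <- 0L

    for (g in seq_len(config$generations)) {
      ord <- order(fits, decreasing = TRUE)
      newpop <- pop[ord[seq_len(config$elitism)]]
      newfits <- fits[ord[seq_len(config$elitism)]]
      while (length(newpop) < np) {
        pick <- function() {
          ij <- sample.int(np, 2L, replace = TRUE)
          if (fits[ij[1]] >= fits[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
        }
        pa <- pick()
        pb <- pick()
        child <- if (stats::runif(1) < config$crossover_rate) {
          oa_crossover(pa, pb, fit1, config$oa_factors)
        } else {
          pa
        }
        child <- mutate_genes(child, config$mutation_rate, config$mutation_step)
        newpop[[length(newpop) + 1L]] <- child
        newfits <- c(newfits, fit1(child))
      }
      pop <- newpop
      fits <- newfits
      if (max(fits) > best_fit) {
        best_fit <- max(fits)
        best_dps <- pop[[which.max(fits)]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      trace[g] <- best_fit
      if (!is.null(trace_file)) {
        f <- fitness_eval(best_dps, initial_aa, cp, cn, config$w_auc, config$w_r)
        cat(sprintf("%d\t%.6f\t%.6f\t%.6f\n", g, f$fitness, f$auc, f$r),
            file = trace_file, append = TRUE)
      }
      if (config$early_stop > 0L && stall >= config$early_stop) {
        trace <- trace[seq_len(g)]
        break
      }
    }
    finish(best_dps, trace)
  })
}

#' Train a scorecard with independent GA restarts
#'
#' Builds the initial scorecard from the labelled training sets, then runs
#' `config$runs` independent [optimize_scorecard()] calls with seeds
#' `seed, seed + 1, ...` and returns the card with the highest training
#' accuracy (ties broken by higher fitness, then by the lowest run index).
#' The GA is stochastic, so independent restarts and selection on training
#' accuracy are the standard protocol. The meta block records a per-run
#' summary table.
#'
#' @param pos,neg Training sequence tibbles or character vectors.
#' @param config A [ga_config()].
#' @param pooling Pooling for the initial card, see
#'   [mean_class_composition()].
#' @return The selected `scorecard`.
#' @export
train_scorecard <- function(pos, neg, config = ga_config(),
                            pooling = c("mean_of_sequences", "pooled_counts")) {
  stopifnot(inherits(config, "ga_config"))
  pooling <- match.arg(pooling)
  initial <- initial_scorecard(pos, neg, pooling)
  cards <- vector("list", config$runs)
  summ <- vector("list", config$runs)
  for (k in seq_len(config$runs)) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    card <- optimize_scorecard(initial, pos, neg, cfg)
    rep <- evaluate_scorecard(pos, neg, card)
    cards[[k]] <- card
    summ[[k]] <- tibble(
      run = k, seed = cfg$seed,
      accuracy = rep$accuracy,
      fitness = card$meta$fitness, auc = card$meta$auc, r = card$meta$r
    )
  }
  summary_tbl <- dplyr::bind_rows(summ)
  acc <- summary_tbl$accuracy
  fit <- summary_tbl$fitness
  best <- which(acc == max(acc))
  best <- best[fit[best] == max(fit[best])]
  sel <- min(best)
  out <- cards[[sel]]
  out$meta$runs_summary <- summary_tbl
  out$meta$selected_run <- sel
  out
}
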