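---
title: "The scoring-card method: model, training and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scoring-card method: model, training and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmseq)
```

## The model

`scmseq` implements an interpretable two-class protein sequence classifier
built on dipeptide composition. The fitted model — a *scorecard* — is a
vector of 400 propensity scores `DPS`, one per ordered residue pair, each
in `[0, 1000]`, together with 20 derived amino-acid scores and a decision
threshold. A sequence `P` of length `L` is scored as

$$S(P) = \sum_{i=1}^{400} w_i \, \mathrm{DPS}_i,$$

where `w` is the dipeptide composition of `P`: the entry for pair `(a, b)`
is `N_{ab} / (L - 1)` with `N_{ab}` the number of positions at which `a` is
immediately followed by `b` (overlapping windows). Since the weights are a
probability vector, `S(P)` is a convex combination of the card's scores and
always lies within its score range; a uniform card scores every sequence at
its constant. A sequence is called positive iff `S(P)` is *strictly*
greater than the threshold — ties are classed negative, the conservative
choice.

This weighted-sum form is what makes the model interpretable: each
dipeptide contributes to the decision in proportion to how often it occurs,
and the score table itself can be inspected (`tidy()`, `autoplot()`),
compared between classes, or painted onto structures.

## Building the initial card

The raw score of each dipeptide is the difference of its mean composition
between positive and negative training sequences. Two aggregation rules are
provided; the default, `mean_of_sequences`, averages per-sequence
composition vectors so that every protein contributes equally regardless of
length. The alternative `pooled_counts` divides summed counts by summed
windows, which weights long sequences more. The per-sequence default was
chosen because class score differences should reflect the typical sequence,
not a handful of long outliers; the pooled variant remains available as an
argument because neither convention is universal in composition-based
classifiers.

Raw differences are min–max rescaled with a *single global* minimum and
maximum over all 400 values,

$$S'_i = 1000\,\frac{S_i - \min S}{\max S - \min S},$$

so the most enriched dipeptide scores exactly 1000 and the most depleted
exactly 0. A per-row (per-first-residue) normalisation was considered and
rejected: the method's published descriptions report a single 0–1000 scale
with single extreme dipeptides, which only the global reading produces.
Numerically, the implementation computes the ratio before multiplying by
1000 so the extremes are attained *exactly* in floating point. If all 400
raw differences are equal — identical classes, degenerate synthetic input —
the normalisation is undefined; the card is then set to 500 everywhere with
a warning rather than an error, so pipelines on pathological inputs can
proceed to a (useless but well-defined) constant classifier.

The amino-acid score of residue `X` is the mean over the 40-slot multiset
of dipeptide scores containing `X`: 20 with `X` first plus 20 with `X`
second, the homodipeptide `XX` therefore counted twice. Whether `XX` should
count once or twice is genuinely open; the 40-slot rule was chosen because
its row/column symmetry yields the exact identity
`mean(aa_scores) = mean(dipeptide_scores)`, which the tests verify on
random cards and which makes the two score scales directly comparable.

The decision threshold maximises training accuracy over all midpoints
between adjacent distinct pooled scores plus sentinels beyond the extremes;
accuracy ties are broken by the larger sensitivity + specificity, then by
the smallest candidate, making the selection deterministic.

## Genetic-algorithm refinement

The 400 scores are refined by a seeded, elitist genetic algorithm whose
fitness balances discrimination against conservation:

$$\mathrm{Fit}(\mathrm{DPS}) = w_{\mathrm{auc}} \cdot \mathrm{AUC} + w_r \cdot R,
\qquad (w_{\mathrm{auc}}, w_r) = (0.9,\, 0.1)\ \text{by default},$$

with AUC the rank-based (Mann–Whitney) area under the ROC curve of the
training scores under the candidate card, and `R` the Pearson correlation
between the initial and candidate amino-acid score vectors. The `R` term
anchors the optimised card to the compositional signal it started from;
with weights `(0, 1)` the initial card is provably optimal (`R = 1`) and
the optimiser returns fitness 1.0, a property the acceptance tests check.
The 0.9/0.1 weighting follows the convention established for scoring-card
classifiers; no sensitivity analysis is published for it, so both weights
are configurable.

Crossover uses **two-level orthogonal arrays**: the 400 genes are split
into `oa_factors` contiguous segments (default 8, sizes differing by at
most one), a Sylvester/Hadamard-constructed array with the smallest power
of two of rows exceeding the factor count prescribes which parent sources
each segment in a small set of trial chromosomes, every trial is evaluated,
and per-factor main effects pick the better-sourced segment for a predicted
child. The better of the best trial and the prediction is returned. This
samples the `2^k` segment-combination space with `O(k)` evaluations instead
of exhaustively. The surrounding generational loop is deliberately plain —
tournament selection of size 2, per-gene uniform mutation (rate 0.01, step
±50 score units, clipped to `[0, 1000]`), elitist carry-over of the 2 best —
because the published method specifies no selection scheme and simple rank
pressure suffices. All stochastic draws come from one seeded generator per
run in a fixed order, so every run is bit-reproducible; the caller's RNG
state is saved and restored.

Because the GA is stochastic, `train_scorecard()` runs `runs` independent
restarts (default 10) with seeds `seed, seed + 1, …` and keeps the card
with the highest training accuracy (ties: higher fitness, then lowest run
index). Fitness is computed on the full training set; cross-validation is
reserved for *reporting* generalisation, not for driving the fitness,
since the published protocol gives no indication of an internal split.

Defaults (population 50, 100 generations, crossover rate 0.8, early stop
after 20 stalled generations) were chosen for desk-scale runtimes: one
restart on 200 + 200 sequences of length 80–300 takes roughly half a
minute on one CPU.

## Evaluation and the composition comparison

`evaluate_scorecard()` reports the confusion counts with accuracy,
sensitivity, specificity, MCC (defined 0 whenever a marginal is zero) and
rank-based AUC. `cross_validate()` shuffles each class with the
configuration seed, splits it into k parts of near-equal size, and re-runs
the full training protocol on each training fold; within folds the number
of GA restarts defaults to 1 so 10-fold runs stay desk-scale — a documented
divergence from the outer multi-restart protocol.

`dipeptide_utest()` compares the per-sequence composition values of every
dipeptide between classes with the two-sided Mann–Whitney U test, the
standard nonparametric choice for skewed, zero-inflated composition values.
The exact null distribution is used when `n·m ≤ 400` and the samples are
tie-free, otherwise the normal approximation with tie and continuity
corrections (the engine is `stats::wilcox.test`; fully tied samples are
reported as `p = 1` directly). Raw p-values are reported without
multiple-testing correction, matching the classical usage; a
Benjamini–Hochberg column is emitted alongside, clearly an extension, for
modern workflows.

## Characterization: scales, tracks, structures

`mine_pcps()` screens AAindex-style physicochemical scales by Pearson
correlation with a card's amino-acid scores. The default keeps scales with
*signed* `r > 0.5` — the convention used when selecting candidate
properties for biological interpretation — while `mode = "absolute"` also
keeps strong anti-correlations. Scales with missing residues can either be
excluded wholesale (`drop_entry`, mirroring the classical removal of
NA-containing indices) or correlated pairwise-complete; both behaviours are
exposed because the literature uses both, sometimes in the same analysis.
The embedded hydration-energy column is only reproducible
pairwise-complete over its 15 measured residues, which is why that is the
fixture default.

`residue_track()` maps a card onto a sequence position-by-position. The
amino-acid source is a lookup; the dipeptide source assigns each position
the mean of its two covering windows (termini use their single window) —
the symmetric choice among the possible per-residue reductions of window
scores, which no published description pins down. `sliding_profile()` is a
centred moving average over full windows only, defined for positions
`(w+1)/2 … L−(w−1)/2`; the default window of 19 residues is the classical
hydropathy-plot convention for locating membrane-spanning helices. The
implementation sums the window then divides once, so constant tracks give
exactly constant profiles.

`annotate_structure()` rewrites the B-factor column (61–66) of `ATOM`
records with the residue's track value divided by 10, mapping the 0–1000
score scale into the 0–100 range that structure viewers colour without
complaint; a `REMARK` documents the scaling. The rewrite is a fixed-column
text substitution, not a parse/re-serialise cycle, so every other byte of
every record — coordinates included — is preserved exactly. Unmappable
residues (waters, ligands, nonstandard residues) receive 0.00 and are
counted in the returned summary.

## The synthetic generator

`generate_sequences()` draws negatives from a first-order Markov chain with
uniform transitions over the 20 residues and positives from the same chain
with selected transition weights multiplied by planted (>1) and depleted
(<1) factors, rows renormalised. Markov generation — rather than i.i.d.
residues with inserted motifs — was chosen because the classifier's signal
is precisely transition-level: enrichment acts multiplicatively on exactly
the quantity the scorecard measures, and the resulting sequences have no
other structure that could confound tests. Defaults are 200 + 200
sequences of length 80–300 (uniform), planted `LF=8, FY=8, DL=6, VE=6`,
depleted `QN=0.1, NE=0.1, NK=0.15` — echoing the extreme dipeptides
reported for membrane-transport proteins so synthetic results are
qualitatively comparable to the real-data narrative.

What passing tests on this generator do and do not show: they demonstrate
that the estimator recovers transition-level enrichment reliably (planted
dipeptides in the top 5 % of scores, held-out AUC above 0.9 at the default
bias), and that the machinery is correct end to end. They do not
demonstrate real-data performance: natural proteins carry length-dependent
composition, domain structure, phylogenetic correlation between training
and test sequences, and much weaker class signals than an eight-fold
transition bias. Published real-data accuracies for this model family (high
70s to low 80s percent) are far below what the synthetic defaults yield,
and no synthetic result here should be read as a real-data claim.

## Numerical and testing choices

* Score computation keeps integer dipeptide counts and divides once, so a
  constant card scores exactly its constant and threshold comparisons are
  not perturbed by summed rounding error.
* Scorecard JSON is written with 17 significant digits, making save/load
  round trips bit-exact; the schema is validated on load with the missing
  key named. Training metadata excludes wall-clock timestamps so that
  identical inputs produce byte-identical scorecard files — the
  reproducibility contract outweighs a provenance nicety.
* Null-signal testing evaluates an initial card trained on 200 + 200
  signal-free sequences against a 1000 + 1000 held-out sample: the larger
  evaluation set shrinks the AUC standard error to ~0.013 so the ±0.05
  no-signal band tests the estimator, not sampling noise.
* Test and acceptance problem sizes: the full GA acceptance run uses the
  generator defaults (200 + 200, one or three restarts); unit tests use
  10–60 sequences with small populations and few generations. The whole
  suite runs in about a minute.

## Known limitations

* The 400-dimensional score vector is estimated from class composition
  differences; with few training sequences per class the initial card is
  noisy and the GA can overfit the training AUC. The multi-restart
  protocol selects on training accuracy, which does not guard against
  this; use `cross_validate()` for honest generalisation estimates.
* Scores are not re-normalised after optimisation, so an optimised card's
  range may be a proper subset of `[0, 1000]`.
* Only the 20-letter canonical alphabet is supported; sequences with
  noncanonical residues are skipped, masked or rejected at input, and
  nucleotide alphabets are out of scope.
* `cross_validate()` with the full multi-restart protocol inside every
  fold is supported (`runs_per_fold`) but slow; the default of one restart
  per fold trades a little variance for tractability.
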