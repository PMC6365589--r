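---
title: "Predicting mature-miRNA processing sites from structured sequences"
author: "matsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mature-miRNA processing sites from structured sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matsite)
```

## The problem

A precursor miRNA (pre-miRNA) is a ~60–120 nt stem-loop from which the
~22 nt mature miRNA is excised by two enzymatic cuts: Drosha defines one
boundary of the mature product, Dicer the other. Given the precursor
sequence and its secondary structure, the task is to locate all four
processing sites — the start and the end of the mature product on the 5'
arm (`P5_5`, `P5_3`) and on the 3' arm (`P3_5`, `P3_3`). Because every
22-nt window of an arm is a plausible product, the classes are heavily
imbalanced (one true site among roughly 15–20 windows per arm), and true
and false windows are nearly identical in sequence; the discriminative
signal is weak and partly structural.

`matsite` addresses this with four per-site classifiers that share one
architecture: structure-aware feature extraction on a gapped duplex
alignment of the stem, univariate feature selection, K-means
centroid-proximity undersampling of the negatives, and an AdaBoost
ensemble of probability-output RBF-kernel SVMs that ranks the candidate
windows of each hairpin.

## The structured sequence

The two stem strands are written as a gapped alignment
(`build_duplex()`): base-paired positions share a column; a nucleotide
bulged out on one strand receives a column whose other strand shows the
absence symbol `-`. Internal loops emit the 5'-side column block first,
then the 3'-side block — the convention is arbitrary, but any fixed
choice only permutes feature columns consistently. The terminal loop is
not columnized; its sequence is kept on the object and supplies flanking
context when anchor-local features run past the loop-side end of the
alignment. Multibranch structures are excluded up front
(`has_multibranch()`): their arms are not well defined as two duplex
strands.

The absence symbol is the load-bearing idea: runs of `-` mark bulges and
internal loops, which destabilize the helix and are known to shape
Drosha/Dicer site choice. Counting and localizing them ("absence
information") gives the classifier access to exactly the structural
signal that a plain sequence window discards; the `sequence_only`
feature mode exists to make that comparison measurable.

The stem base is extended by 10 artificial perfectly-paired columns
(`extend_stem()`), so that windows and anchor-local features near the
base have well-defined flanking context. The padding uses alternating
G-C/C-G pairs: maximally stable pairing semantics without creating a
homopolymer, since the original report does not name the bases. Padding
columns carry no arm coordinate and are never candidate anchors.

## Candidate windows and features

`enumerate_candidates()` slides a 22-nt window along the arm, one
candidate per admissible anchor. Start-site models anchor the window at
its 5' end, end-site models at its 3' end; windows never cross the
terminal loop. The 22-nt span is stated for 5'-arm start sites in the
source method; we assume the same span for the other three site types by
symmetry. The candidate matching the annotated mature start (or end) is
the single positive of the hairpin.

`extract_features()` produces a 101-feature vector per candidate:
own-strand and opposite-strand composition over the structured alphabet
`{A,C,G,U,-}` (mono- and dinucleotide, gap-containing pairs pooled),
column-state fractions (paired / 5'-bulge / 3'-bulge / internal loop),
absence counts in the window and 10 columns up- and downstream, gap-run
statistics per strand, one-hot structured symbols at offsets −2..+2 on
both strands around the anchor, pairing states at offsets −3..+3, column
distances to the terminal loop and the stem base, window GC content, and
the window pairing fraction. The original feature set is described only
by category (and counts 115 features); this catalog is a reconstruction
of those categories at the same order of dimensionality, and the
extractor is written so alternative catalogs can be tested. Fractions
rather than raw counts keep windows with gap-inflated column spans
comparable.

`sequence_only` mode (45 features) drops everything that depends on `-`
or pairing; it is the ablation that quantifies what structure adds.

## Feature selection

Three univariate scores are implemented (`score_features()`):

* **Information gain** — mutual information, in bits, between the
  binarized feature and the class.
* **Chi-square association** — the cross-product difference of the 2×2
  joint table normalized by all four marginals, per class, combined by
  max. This is the literal published form (no squared numerator, no
  sample-size factor); it orders features identically for fixed
  marginals.
* **Relief** — the classic Kira–Rendell weight: probe samples move each
  feature weight away from the nearest-hit difference and toward the
  nearest-miss difference, with min-max normalized coordinates,
  Euclidean neighbors, and `m = min(N, 200)` seeded probes.

IG and CHI need discrete features; continuous features are thresholded
at their training-set median (`binarize()`), a choice the source method
leaves unstated; medians are stored and reused for test data. Features
scoring ≤ 0 are deleted (`rank_and_select()`); the pipeline defaults to
information gain, which the source method also adopted after comparing
the three. One-hot features that are constant in training are flagged
degenerate and score 0, so they drop out.

## The weak learner: probability-output RBF-SVM

The weak classifier is a soft-margin SVM with kernel
`K(x, x') = exp(-g ||x - x'||^2)`. Because AdaBoost reweights samples
each round, the dual is solved with per-sample box constraints
`C_i = C · w_i · N` (weighted hinge loss) — deterministic, unlike
resampling. No packaged R solver accepts per-sample penalties, so the
dual is solved by a dedicated SMO implementation (maximal violating
pair, dense kernel, KKT gap tolerance `1e-3`); at uniform weights it is
cross-checked against `e1071::svm` in the test suite.

Margins are mapped to probabilities by a sigmoid fitted on training
margins with Platt's regularized targets (quasibinomial IRLS), and the
pairwise estimate is passed through the probability-coupling quadratic
program: minimize `sum (r_ji P_i - r_ij P_j)^2` subject to
`sum P_i = 1`, solved via its KKT linear system. For two classes the
solution collapses to the closed form `P(+1) = r`; the general solver is
implemented and tested so the QP path is exercised, with a normalized
diagonal fallback (flagged) if the system is singular.

Per round, `(C, g)` are chosen by exhaustive grid search with weighted
cross-validated accuracy, ties toward smaller `C` then smaller `g`. The
`grid_search()` defaults are the conventional ranges
`C ∈ 2^{-5..15}`, `g ∈ 2^{-15..3}` (step `2^2`); the training pipeline
defaults to a reduced 3×3 grid (`C ∈ 2^{-1,3,7}`, `g ∈ 2^{-7,-3,1}`)
with 2-fold CV and a seeded stratified cap of 600 samples per CV fit —
sizes chosen so a full benchmark trains in seconds while still spanning
three orders of magnitude in each parameter. The final model of a round
always uses all subset samples.

## Balancing and boosting

With ~1:15 imbalance, a plain SVM degenerates toward the majority
class. `kmeans_balance()` clusters the negatives into `threshold = 10`
groups by explicit Lloyd iterations (Euclidean assignment, mean
centroids, stop when assignments stabilize; empty clusters are re-seeded
at the farthest sample) and keeps, from each cluster, the samples
nearest its centroid. Per-cluster quotas are allocated by largest
remainder so the total is exactly `floor(n/10)` — one tenth, matching
the 1:10 imbalance the threshold presumes. Keeping centroid-proximal
representatives preserves the modes of the negative distribution
instead of sampling it at random.

`adaboost_train()` then runs AdaBoost with the weak SVM: uniform initial
weights `1/N`; round `t` trains on
`S_t = S_pos ∪ S_neg1 ∪ (all previously misclassified samples)`; weak
predictions are relabeled per hairpin (the max-probability candidate is
+1, all others −1 — the biological constraint that each arm holds one
product), both inside training error and at prediction; the weighted
error `e_t` over all samples gives `alpha_t = ½ ln((1-e_t)/e_t)` and the
exponential weight update, normalized each round. Natural log is used —
the base only rescales all `alpha_t` and cancels in ranking. `e_t ≥ 0.5`
discards the round and stops; `e_t = 0` caps `alpha_t` at the value for
`e = 1/N`, keeps the round, and stops. `T` defaults to 10 in
`adaboost_train()` (the source method never states `T`); the pipeline
and benchmark use `T = 5` with early stopping, which the boosting
histories show is already past convergence on the synthetic task.

The ensemble ranks candidates by the alpha-weighted mean of weak
probabilities. The integrated classifier of the source method is a hard
sign, but the task requires a graded top-five output; the weighted mean
of calibrated probabilities is its natural probabilistic reading, and
the hard sign is reported alongside.

## Evaluation

`deviation_table()` reports, for each deviation `d = 0..5` nt, the
fraction of hairpins whose rank-1 candidate (and whose best of the top
five, minimum |deviation| with ties to the higher rank) misses the true
site by exactly `d`, plus the cumulative total within 5 nt and the
average position deviation (APD). Exact accuracy is the `d = 0` cell of
the first-candidate row. `stratify_by_absence()` bins hairpins by
whole-duplex absence counts (0–2, 3–5, 6–8, 9–11, 12+) to show how
bulge content degrades identification.

## The synthetic benchmark

`generate_dataset()` builds seeded hairpins column-by-column: paired
columns with probability `1 - bulge_rate` (10% G-U wobbles), single-
strand bulges otherwise, a terminal loop of 8–12 nt, arms of 36–44 nt,
and a true 22-nt mature interval placed uniformly on the arm. A 5-nt
motif is written at offsets −2..+2 around the true start and end, and
bulges there are suppressed, each independently with probability
`signal_strength` — so the planted signal is part sequence, part
structure, and its strength is a dial from pure noise (0) to fully
deterministic (1). Structures are emitted by construction, not by
folding, so no folding engine is needed anywhere in the tests.

The benchmark conditions are 200 training and 100 test hairpins,
`signal_strength = 0.9`, `bulge_rate = 0.08`, `T = 5`: a regime where
the signal is strong but not deterministic and the candidate imbalance
(~1:17) matches the real task's order. What passing this benchmark
shows is that the pipeline recovers a planted, locally-encoded signal
through the full stack — alignment, features, selection, balancing,
boosting, ranking — and that the structured features and the balancing
step do not hurt. What it cannot show is performance on real
precursors: synthetic hairpins have uniform base composition, motif
signals far cleaner than biological Drosha/Dicer determinants, and
construction-generated (not thermodynamic) structures. Published
accuracies on miRBase-derived sets are therefore not comparable to the
synthetic numbers.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere, matching miRBase
  convention and R idiom; readers and writers do no conversion.
* **Multiple matures on one arm**: the first annotation is used, the
  rest are logged — the source data format does not define a
  tie-break.
* **Matures straddling the terminal loop** are excluded: their windows
  would cross the loop and have no duplex representation.
* **Anchor-local offsets** past the loop-side end of the alignment are
  filled from the terminal-loop sequence; past the base-side end they
  fall on stem padding. An offset overrunning the loop is an error
  rather than a silent zero.
* **SMO**: stopping gap `1e-3`, bias from the converged violating-pair
  bounds, support vectors kept at `alpha > 1e-12`.
* **Grid-search ties** go to the smallest `C`, then the smallest `g`
  (the least-complex model among equals).
* **Seeding**: every stochastic step (generation, splits, fold
  assignment, Relief probes, centroid seeding) takes an explicit seed
  and restores the caller's RNG state.

## Limitations

Only single-stem hairpins are modeled; pseudoknots and multibranch
precursors are out of scope. The feature catalog is a reconstruction —
the exact published 115-feature set is not enumerable from its
description. Window length 22 is assumed for all four site types. The
balancing threshold presumes roughly decade imbalance; for very short
arms the floor quota can underfill a cluster. Real-data performance
requires real training data through the same interfaces (FASTA, RNAfold
output, annotation TSV).
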