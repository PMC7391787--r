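---
title: "Classifying antioxidant proteins by vote-stacked SVMs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying antioxidant proteins by vote-stacked SVMs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antioxvote)
```

## The problem

Antioxidant proteins neutralize reactive oxygen species; finding them among
the mass of uncharacterized sequences is a binary classification task:
given only an amino-acid sequence, predict antioxidant (+1) or not (−1).
`antioxvote` implements a sequence-only classifier built from two
composition-style feature families, univariate feature selection, and a
stacked ensemble of radial-basis support vector machines.

## Feature encodings

**g-gap dipeptide composition.** For a gap `g` in 0..9, every ordered residue
pair `(a, b)` whose positions differ by `g + 1` is counted; the 400
frequencies are `count / (L − g − 1)` for a sequence of length `L`, so the
vector is a normalized composition whenever `L > g + 1`. `g = 0` is the
classical adjacent-dipeptide composition; larger gaps capture longer-range
residue correlations.

**Reduced amino-acid n-peptide composition.** Five built-in cluster profiles
partition the 20 amino acids into `k` physicochemical groups
(`Op5`, `Op8`, `Op9`, `Op11`, `Op13` with `k` = 5, 8, 9, 11, 13). A sequence
is first rewritten over the `k` representative letters, then its overlapping
n-peptides are counted and normalized by `L − n + 1`. The peptide order
defaults to the value found best for each profile: `n = 3` for `Op5`
(dimension `5^3 = 125`) and `n = 2` for the others (64, 81, 121, 169);
`Op5` dipeptides give 25 features. The published source for `Op11` contains
a typesetting garble in the group list; the package uses the only reading
that yields 11 groups covering all 20 letters,
`{G; IV; FYW; A; LM; EQRK; P; ND; HS; T; C}`.

Two conventions are the package's own, since any fixed choice works as long
as it is stable across training and prediction: features are ordered
lexicographically (over the plain alphabet for g-gap, over sorted
representative letters for reduced n-peptides, visible in feature names such
as `"AC|g2"` or `"GII|Op5"`); and the normalizer for the reduced composition
is `L − n + 1`, mirroring the g-gap normalizer, which makes every emitted
vector sum to 1. Sequences shorter than an encoder's minimum (`g + 2`, or
`n`) raise an error naming the record rather than being zero-filled.

## Feature selection

Each feature is scored by the one-way two-group ANOVA F-value, the ratio of
between-class to within-class variance; for two groups this equals the
squared pooled-variance t statistic, which the test suite verifies
numerically. Degenerate features follow fixed conventions: constant
everywhere → `F = 0`; constant within each class but different between
classes → `F = +Inf`, ranked above all finite scores; remaining ties break
lexicographically by name.

Incremental feature selection (IFS) then walks the ranking: for each subset
size `k` the top-`k` features are evaluated and the smallest `k` attaining
the maximum accuracy is kept. The evaluator inside IFS is stratified 5-fold
cross-validation with a fixed SVM configuration obtained by one grid search
on the full feature set — re-running the grid search at all 400 subset sizes
would be quadratic-cost for no documented benefit, and a nested search can
be reproduced by calling `grid_search()` per subset where needed. Jackknife
can be substituted via `make_cv_evaluator(method = "jackknife")`.

## Classifiers and evaluation

All classifiers are C-classification SVMs with the radial-basis kernel
(via libsvm). Compositions already live in `[0, 1]`, so no feature scaling
is applied. Hyperparameters come from a grid search over the standard
coarse lattice `C = 2^-5, 2^-3, ..., 2^15`,
`gamma = 2^-15, 2^-13, ..., 2^3`, scored by stratified k-fold accuracy with
deterministic tie-breaking (best accuracy, then smallest `C`, then smallest
`gamma`). No class weighting is applied by default even for imbalanced
data — this matches the low-sensitivity/high-specificity operating profile
the pipeline is known for; weights can be emulated upstream by subsampling.

Evaluation reports sensitivity, specificity, accuracy and the Matthews
correlation coefficient from the pooled confusion counts. Degenerate
denominators are set to 0 and flagged rather than raised. The jackknife
evaluator performs a full leave-one-out loop (deterministic); stratified
k-fold is available where the jackknife's quadratic cost is unwarranted.

## The vote-stacking ensemble

The full pipeline trains 15 base models on the training split: one g-gap
model per gap 0..9 (each with ANOVA + IFS feature selection) and one
reduced-alphabet model per profile (full feature set by default — whether
those should also undergo IFS is genuinely open; the package exposes
`ifs_raac = TRUE` but defaults to the literal construction). Each base
model's sensitivity is measured on the held-out test split, and models
below the 0.20 sensitivity threshold are dropped (configurable). The
retained models — nine of them in the original construction, hence
9-dimensional vote vectors there — re-encode every sequence as an ordered
±1 vote vector, and a final grid-searched SVM is trained on those votes.

How the *training* votes are produced is unstated in the construction this
package implements, and predicting one's own training data leaks
information, so the default is out-of-fold stacking: within the training
split, each base model is re-fitted on 4/5 of the data (same encoder,
features and hyperparameters) to vote on the held-out fifth. The deployed
base models are frozen; cross-fitting only generates training votes. A
`"resubstitution"` mode reproduces the literal construction. Retained-model
order is the construction order (gaps ascending, then profiles) and is
persisted, since the final classifier is order-sensitive.

## Synthetic data

The generator emulates the shape of the antioxidant benchmark this method
family is trained on: 253 positives versus 1,552 negatives by default, with
lengths drawn uniformly from 30–500 (inside the benchmark's 11–1463 span
while long enough for every encoder up to `g = 9`). Negatives are i.i.d.
residues from a background table (uniform 1/20 by default — the simplest
null; a natural-abundance table is available). Positives add a first-order
dependence at the configured lag: whenever the residue `g + 1` positions
back matches the first member of a planted ordered pair, the emission
probability of the second member is multiplied by `1 + effect` and
renormalized. The planted pairs therefore map one-to-one onto features of
the chosen encoding, making signal recovery directly checkable. Defaults
where the design was open: `effect = 2`, the strength at which the planted
pairs are reliably recoverable by the F ranking, and 10 planted pairs,
keeping the signal sparse relative to the 400-feature space.

What the generator does *not* emulate: real protein composition biases,
motifs, domains, phylogenetic redundancy, or the 60% identity filtering of
curated benchmarks. Passing tests on synthetic data therefore demonstrate
that the machinery is correct and that planted compositional signal is
recovered — not that any particular accuracy will be achieved on real
antioxidant data.

## Numerical and operational choices

- Splits are stratified by class with an explicit seed (default 42);
  per-class training counts are `round(fraction * n_class)`.
- All seeded operations restore the caller's RNG state.
- Non-standard residues (B, J, O, U, X, Z, gaps, `*`) are dropped with a
  warning by default (`strict` mode errors instead), since real database
  entries commonly contain them.
- Labels are ±1 throughout, matching the vote-vector convention.
- Feature-vector sums are exact rational counts divided by an integer, so
  the sum-to-1 property holds to machine precision (tested at 1e−9).

## Scales used by the test suite

The shipped tests run the full machinery at reduced problem sizes chosen to
exercise every code path while keeping the suite quick on a single CPU:
encoder/oracle comparisons on 200 random sequences of length 12–60;
selection and modeling properties on matrices of tens of samples; signal
recovery at 100+100 sequences over 5 seeds; ensemble behavior with three
base models (two gaps plus one profile) on datasets of 100–200 sequences.
The headline benchmark of the original construction is not redistributable,
so no test asserts its published performance numbers; the package's claims
are the structural and statistical properties above.

## Known limitations

- IFS evaluates a fixed hyperparameter configuration along the curve;
  features whose value only shows under different hyperparameters may be
  ranked low.
- The sensitivity filter is measured on a single held-out split; with small
  test sets the retained-model set can vary between seeds.
- The synthetic generator's first-order signal cannot express interactions
  between multiple planted pairs at different lags within one class.
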