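---
title: "Formula-only LogP modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formula-only LogP modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FormulaLogP)
```

## The problem

The octanol–water partition coefficient, reported as its base-10 logarithm
LogP, quantifies how a compound partitions between a lipophilic and an
aqueous phase. It drives environmental fate (soil sorption of halogenated
pollutants), drug bioavailability (the "rule of five" caps oral drugs at
LogP 5), and separations design. Essentially every predictive LogP model —
fragment-additive schemes, similarity-search methods, molecular-simulation
descriptors — takes the molecular *structure* as input. But in several
settings only the molecular *formula* is known: high-resolution mass
spectrometry of complex mixtures (FT-ICR-MS, MALDI) resolves elemental
composition without structure, and early discovery scans may enumerate
candidate formulas before structures exist.

FormulaLogP implements and evaluates the formula-only alternative: engineer
every feature a formula supports, fit standard regressors, and measure how
much accuracy structure-blindness actually costs. Its accuracy ceiling is
set by isomers — compounds sharing a formula are indistinguishable to any
formula-only model, so the spread of LogP across isomers (typically around
half a log unit on mined datasets) bounds what any member of this model
class can achieve. This bound is measurable with `isomerDeviation()` and is
itself part of the analysis.

## Feature engineering

From a parsed formula the package derives at most 21 features, in a frozen
column order:

1. **Atom counts** (columns 1–10): the number of C, H, N, O, S, P, F, Cl,
   Br, I atoms. Ten elements define the supported alphabet; formulas with
   any other symbol are rejected outright rather than silently truncated,
   because a dropped element would silently move a compound to a different
   point of the feature space.
2. **Elemental ratios** (columns 11–19): H/C, N/C, O/C, S/C, P/C, F/C,
   Cl/C, Br/C, I/C. Defined only for organic (carbon-containing)
   compounds; carbon-free records are a curation error, not a modeling
   input. A C/C column would be constant 1 and is not included, which is
   why the extended width is 10 + 9 + 2 = 21.
3. **Molar weight** (column 20): the count-weighted sum of fixed
   conventional atomic weights (C 12.011, H 1.008, N 14.007, O 15.999,
   S 32.06, P 30.974, F 18.998, Cl 35.45, Br 79.904, I 126.904). The table
   is version-stamped into feature matrices and saved models so that a
   future weight revision cannot silently shift the MW column.
4. **Double-bond equivalents** (column 21): rings plus degrees of
   unsaturation, DBE = C − (H + halogens)/2 + N/2 + 1. Benzene (C6H6) has
   DBE 4, cyclohexyne (C6H8) has DBE 3, and every alkane has DBE 0.
   Chemically inconsistent formulas (radicals, salt fragments in mined
   data) can produce negative or half-integer DBE; these pass through with
   a warning because the regressors treat DBE as a plain numeric column
   and rejecting such rows would shrink mined datasets unpredictably.

Note that MW and DBE are exact linear combinations of the ten counts, and
the ratios are deterministic nonlinear transforms. The extended matrix
therefore carries no new information for a tree model and is exactly
rank-deficient for a linear one — which is precisely why comparing
base-versus-extended fits is an experimental factor rather than an obvious
win (see the factorial design below), and why the linear fitter falls back
to a minimum-norm solution with a warning instead of failing.

## Curation rules

Mined LogP collections need two filters before modeling:

- **Inorganic removal**: operationalized as "no carbon". This is the
  broadest rule consistent with a model whose ratio features require
  carbon; CCl4 is organic by this definition, water is not.
- **Duplicate removal**: a record is a duplicate only if it matches a kept
  record on the exact (canonical identity, LogP) pair, where identity is
  the SMILES string when present and the (name, Hill formula) pair
  otherwise. Repeated measurements with *different* values are retained
  deliberately — they carry the experimental variance — as are isomers
  sharing a formula, which carry the isomer spread the model must live
  with.

Curation is idempotent, counts its removals in a provenance record, and
refuses to return an empty dataset. Train/held-out splitting uses the floor
rule for the training size: `floor(fraction * N)`, the unique convention
consistent with both an 85% split of 18,091 records giving 15,377/2,714
and an 80% split of 15,377 giving 12,301/3,076.

## The six regressors

All six are fitted behind one `ModelSpec`/`fitModel()`/`predict()` surface:

- **MLR** — ordinary least squares with intercept (QR; SVD minimum-norm
  fallback under rank deficiency).
- **Ridge** — minimizes RSS + λ·Σβ², intercept unpenalized, by direct
  solve of the penalized normal equations.
- **Lasso** — minimizes RSS + λ·Σ|β| by cyclic coordinate descent with
  exact soft-threshold zeros; non-convergence warns with the sweep count.
- **Random forest** — mean over B bootstrap trees with squared-error
  splitting (via the randomForest package); depth is controlled through
  the maximum leaf count (2^depth).
- **Gradient boosting** — stagewise depth-limited trees fitted to running
  residuals with shrinkage, initialized at mean(y) (via xgboost, single
  thread, no subsampling, no leaf regularization, so each stage is an
  exact shrunken residual fit and training RSS is non-increasing in B).
- **KNN** — unweighted mean of the K training responses nearest in
  unscaled Euclidean distance, with ties at the K-th distance broken by
  the lowest training index. Distances are deliberately unscaled: atom
  counts share a natural unit (atoms), and no standardization step is part
  of this model's definition.

### Penalty conventions — a deliberate asymmetry

`fitRidge()` and `fitLasso()` take λ in the raw objectives written above,
so the textbook closed forms hold exactly (a centered one-feature ridge fit
returns Σxy/(Σx²+λ); a one-feature lasso returns the soft-thresholded OLS
solution). Two switches re-express λ in the conventions common Python
toolkits use: `standardize` applies the penalty on unit-variance columns,
and `perObservation` rescales λ to an objective normalized by the sample
size.

The *default* (untuned) specs mirror those toolkit defaults faithfully,
and the two defaults genuinely differ: the reference implementation defines
its unit ridge penalty on the raw RSS — negligible against a residual sum
over thousands of observations, so a default ridge fit is indistinguishable
from plain least squares — while its unit lasso penalty is per-observation
on standardized columns. A per-observation unit lasso penalty zeroes
*every* coefficient whenever max over features of |cor(x, y)|·sd(y) < 1.
Formula-only LogP data sits in exactly that regime (single-feature
correlations are weak because LogP is not a function of composition alone),
so the default lasso collapses to the intercept-only model with training
R² exactly 0. This is reproduced, not patched around: it is the documented
behavior of an untuned lasso on this problem, and tuning λ restores a
lasso comparable to MLR/ridge.

### Defaults and tuning grids

Default hyperparameters: random forest B = 100 trees, unrestricted depth,
bootstrap on; gradient boosting B = 100 stages, learning rate 0.1, depth 3;
K = 5 neighbours; λ = 1 for ridge/lasso in the conventions above. All are
overridable through `modelSpec()`.

`tuneModel()` runs an exhaustive grid search scored by mean validation RMSE
over 8 cross-validation folds. Folds are contiguous blocks of a seeded
permutation — deterministic, and unstratified because the response is
continuous. Ties are broken by grid order; a candidate infeasible on a fold
(K larger than the fold's training size) scores +Inf rather than aborting
the search. Two grid sets ship with the package: `defaultGrids("full")`
(λ ∈ 10^−4..10^4, B ∈ {100, 250, 500}, depth ∈ {3, 5, 10, ∞}, K ∈ 1..25;
boosting depth capped at 10 because an unrestricted-depth weak learner is a
contradiction) and `defaultGrids("desk")`, a compact subset used as the
default for desk-scale experiments.

## The factorial training-protocol experiment

`runFactorial()` crosses three binary factors over all 8 combinations, per
model kind:

1. **extended features** — 21 columns versus 10;
2. **cross-validation** — the *training* performance estimate comes from
   8-fold cross-validation within the training partition, versus from
   refitting on the training data (validation metrics always come from the
   held-out 20%, from the same full fit either way);
3. **tuned hyperparameters** — the tuned spec versus the default spec.

Two structural decisions deserve explanation. First, tuning runs *once* per
(model kind, feature set) on the full training pool before the repeat loop,
producing a fixed tuned-hyperparameter table; the repeated cells then reuse
it. Tuning inside every repeat would multiply the cost roughly eightfold
and answer a different question (stability of the tuner, not quality of
the protocol). Second, the outer test partition (15%) is split off once
and frozen before the experiment; only the inner 80/20 split is
re-randomized across repeats, each repeat's seed derived from the master
seed by a fixed increment so any single repeat is reproducible in
isolation.

`selectFinal()` picks the cell with the smallest mean validation RMSE, but
treats any cell within one pooled standard deviation of the minimum as
statistically indistinguishable and then prefers fewer features, then fewer
tuning steps — a parsimony rule: when the 21-column model is within error
of the 10-column one, the 10-column model wins.

## The synthetic generator

`generatorSpec()`/`simulateLogPDataset()` generate formula/LogP records
with known structure so every pipeline stage is testable without any
external download. Element counts are drawn to mimic the shape of mined
LogP collections: carbon 1 + negative-binomial (mean near 10), capped at
62; heteroatoms sparse (most counts zero); hydrogen derived from carbon,
nitrogen, halogens and a drawn unsaturation count so every formula is
chemically consistent. The response is **atom-additive**: a linear
combination of the ten counts plus an intercept, plus a per-record isomer
offset (SD `sigmaIso`, default 0.45 — each record plays the role of a
distinct isomer of its formula) plus measurement noise (SD `sigma`,
default 0.3, the floor reported for shake-flask measurements). The
defaults were calibrated once so that the generated data reproduce the
statistical regime of mined LogP datasets — per-formula isomer spread near
0.46 log units, weak single-feature correlations with carbon the strongest
positive and N/O negative — and then frozen.

The generating coefficients live on the count block only, with zeros on
the ratios, MW and DBE. This is a deliberate identifiability choice: MW
and DBE are linear in the counts, so weight placed there could be moved
into the count coefficients without changing any prediction, and
"recovering the generating coefficients" would be ill-posed. With an
atom-additive truth, a noise-free linear fit on the base features recovers
the coefficients to machine precision — the package's strongest end-to-end
correctness check.

What the generator does *not* emulate: the real nonlinearity of LogP in
composition (the true relationship is only partly additive), the
correlated occurrence of heteroatoms within compound families, realistic
name/SMILES metadata, and the long tail of data-entry pathologies in mined
sources. Passing tests on synthetic data therefore demonstrate the
correctness of the machinery and the qualitative protocol behavior
(overfitting patterns, penalty regimes), not real-data accuracy figures.
Contamination switches (`duplicateRate`, `inorganicRate`) inject exact
duplicates and carbon-free records so the curation filters can be tested
quantitatively.

## Functional-group stratification

A formula-only model cannot see functional groups — which is exactly why
its errors are stratified by them afterwards. `detectGroups()` one-hot
encodes eight coarse classes (aromatic, carbonyl, alcohol, amine/nitrile,
unsaturated aliphatic, ether/ester, halogenated, other heteroatom) by
SMARTS substructure matching on SMILES strings, via OpenBabel through
ChemmineR/ChemmineOB. The pattern list (`functionalGroupPatterns()`) is an
explicit, documented stand-in taxonomy: deliberately coarse (the alcohol
pattern also hits phenols and carboxylic hydroxyls), with multi-membership
expected — a molecule contributes to every group it matches, so group
counts sum to more than N. Error summaries report n, mean, median and the
5th/95th percentiles with linear interpolation between order statistics
(the R type-7 default). SMILES handling is confined to this module; the
predictive path never touches structure.

## Numerical choices, degenerate inputs, problem sizes

- Formula parsing is case-sensitive recursive descent with arbitrary
  nesting; zero multiplicities, charges, isotope markers and hydrate dots
  are syntax errors. Errors carry the offending symbol or position.
- Coordinate descent converges on the maximum coefficient update
  (tolerance 1e-10 scaled by the response magnitude, 100,000-sweep cap
  with a warning on expiry); soft-thresholding makes exact zeros, so
  "all coefficients zero" is a literal statement, not a small-number one.
- `evaluateModel()` requires at least two observations and computes R²
  against the mean of the *evaluated* partition; a constant-mean
  prediction scores R² exactly 0 by construction.
- Splits and every stochastic fit run under explicit seeds through a
  wrapper that restores the caller's RNG state, so library calls never
  perturb user code.
- Desk-scale problem sizes used by the shipped test suite: synthetic
  datasets of 260–6,000 records for unit and property tests, and a
  factorial run of n = 2,000 records, 10 repeats per cell, desk grids —
  48 cells (8 factor combinations × 6 models) in a few minutes on one
  CPU. Full-scale analyses (tens of thousands of records, 100 repeats,
  full grids) use the same code paths through the `experiment` CLI
  subcommand.

## Limitations

- The accuracy ceiling is structural: isomers are indistinguishable, so
  no amount of tuning can beat the isomer spread of the data.
- The ten-element alphabet excludes organometallics, boron and silicon
  chemistry entirely — by design, but worth restating.
- The functional-group taxonomy is a stand-in; two reasonable chemists
  could draw the classes differently, and conclusions about per-group
  error should be read at that granularity.
- Charged species have no canonical formula representation here; explicit
  charge tokens are rejected, so salts must be entered as neutral
  formulas or not at all.
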