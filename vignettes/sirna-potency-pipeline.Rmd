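---
title: "Predicting siRNA potency: features, forests and SVMs"
author: "sirnaforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting siRNA potency: features, forests and SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnaforest)
```

## The model

An siRNA instance is a 19-nt antisense (guide) sequence read 5'→3',
without the 3' two-nucleotide overhang, together with the remaining
relative mRNA level of its target after treatment (0 = complete
silencing, 1 = no effect). The binary potency label is a pure threshold:
potent ("positive") if and only if the level is at most 0.5, with the
boundary included. Input sequences may use DNA letters; they are
uppercased and `T` is mapped to `U` before validation, because published
siRNA tables are written in either alphabet.

The pipeline has three stages — a fixed 120-feature encoding, importance
-based feature selection by an ensemble of random forests, and an
RBF-kernel support vector machine — evaluated by stratified fivefold
cross-validation on pooled held-out predictions.

## The 120-feature encoding

Six groups, in a fixed schema order (`feature_schema()`):

| group | size | definition |
|---|---|---|
| positional codes `NT1..NT19` | 19 | nucleotide identity at each position, coded A = 0.1, U = 0.2, G = 0.3, C = 0.4 |
| mononucleotide `A%..C%` | 4 | base frequencies over 19 positions |
| dinucleotide `AA%..CC%` | 16 | frequencies over the 18 overlapping windows |
| trinucleotide `AAA%..CCC%` | 64 | frequencies over the 17 overlapping windows |
| G/C content `GC_overall`, `GC_w1..GC_w15` | 16 | overall G/C fraction and the 15 sliding windows of five nt (window 1 is the 5'-terminal "first 5 bases" feature) |
| `MFE` | 1 | minimum free energy of predicted secondary structure, kcal/mol, ≤ 0 |

Two conventions in this encoding were genuinely open and are fixed here
deliberately. First, "frequency" is taken as count divided by the number
of overlapping windows (19, 18 and 17 for k = 1, 2, 3), so every
composition group is a probability vector; raw counts would only rescale
each group by a constant and would make group totals depend on k.
Second, k-mer windows overlap — disjoint windows could not produce 18 or
17 windows on a 19-nt sequence, and overlapping scans are the standard
composition feature for short sequences. All k-mer orders use the
alphabet order A < U < G < C.

### Folding backends

The `MFE` feature delegates to a pluggable backend. The default,
`nussinov_backend()`, is a maximum nested base-pairing model: pairs AU,
GC and GU (wobble), a minimum hairpin loop of three unpaired bases, and a
score of −1 kcal/mol per pair. This is a *structural stand-in*, not a
thermodynamic nearest-neighbor model: it preserves the feature's
semantics (more pairable self-structure gives a lower energy, and a
sequence admitting no pairs scores exactly 0) while keeping the package
free of external dependencies. `rnafold_backend()` adapts any
ViennaRNA-compatible `RNAfold` executable when thermodynamic energies
are wanted; both backends are deterministic, and the choice is recorded
in run manifests. Nineteen-mers rarely fold into deeply stable
structures, which is consistent with this feature ranking low in
importance.

## Random-forest feature selection

Each forest grows `B` CART trees (Gini impurity, binary threshold splits
at midpoints between consecutive observed values, unlimited depth,
minimum leaf size 1) on bootstrap samples of size *n* drawn with
replacement; at every node `m` candidate features are drawn uniformly
without replacement. These growing rules are the classical
random-forest defaults; the positional codes {0.1, 0.2, 0.3, 0.4} are
treated as plain numerics, which is exactly what their real-valued
encoding implies. Ties in the split search resolve to the lowest feature
index and lowest threshold; leaf-majority ties resolve to the negative
class. A tree's out-of-bag (oob) set — the instances absent from its
bootstrap, about one third of the data — acts as its internal test set.

Importance of feature *j*: for each tree, the number of oob instances
classified correctly minus the number classified correctly after
permuting column *j* within that tree's oob rows only. The per-tree
scores are averaged to the raw score; dividing by their standard error
(sd/√B) gives the z-score used for ranking, with z defined as 0 when the
standard error is 0 (a feature unused by every tree is exactly such a
case: its permutation cannot change any decision path, so its raw score
is identically zero). A normal-approximation p-value is reported
informationally next to the z-score but plays no role in selection —
only the top-20 ranking does.

The consensus protocol fits one forest per
m ∈ {2, 3, 5, 7, 9, 11, 13, 15, 17, 20} (ten forests, default B = 1000),
records each forest's top 20 features by z-score, and selects the
features chosen by at least 5 of the 10 forests. The ten forests are
seeded independently from the master seed (one derived substream per
forest for growing and one per forest for permutations), so whole runs
are exactly reproducible; whether the original protocol shared seeds
across forests is unknowable from the outside, and independent seeding
is the natural default. Class imbalance is left unweighted, matching the
classical algorithm.

## The SVM classifier

The classifier is a soft-margin SVM with kernel
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$, defaults
$\gamma = 1.2$ and $C = 1.2$; a grid search over
{0.1, 0.3, 0.6, 1.2, 2.4, 4.8} for both parameters by cross-validated
AUC is available (`tune_svm()`). The quadratic program is solved by
libsvm (via e1071); the package stores the support vectors, dual
coefficients and bias and computes decision values from its own kernel
expansion, oriented so that positive values mean potent.

Scaling: all composition, positional and G/C features already live in
[0, 1] and are passed through unchanged; the MFE feature (negative
kcal/mol) is min-max scaled to [0, 1] with training-set bounds stored in
the model, so the default γ operates on comparable coordinates at train
and predict time. The classifier consumes raw feature values restricted
to the selected subset — not importance scores.

## Evaluation

Positive and negative instances are distributed randomly into five folds
*within each class* (stratified; plain randomization is available).
Stratification guarantees both classes in every training split at the
dataset sizes in play. Predictions from the five held-out folds are
pooled once, and all measures are computed on that pooled set: accuracy,
sensitivity and specificity in percent, the Matthews correlation
coefficient, the ROC curve from a threshold sweep over all distinct
decision values (tied scores move together, making the trapezoidal area
identical to the rank-based Mann–Whitney AUC — an identity the tests
assert to 1e-10), and the Pearson correlation between decision values
and the inhibition level 1 − remaining mRNA. A metric whose denominator
is zero (e.g. MCC when a confusion row or column is empty) is reported
as 0 and flagged rather than erroring, so degenerate folds surface in
reports instead of aborting them.

By default, feature selection runs once on the full dataset before
cross-validation. That mirrors the reference protocol, but it lets the
selection stage see the evaluation folds, so CV metrics inherit an
optimistic bias; `run_all(nested = TRUE)` redoes the selection inside
every training fold for leak-free estimates at about five times the
cost. The package takes no position on which variant the original
protocol intended; both are provided.

## The synthetic-data generator

Real siRNA efficacy compilations are generally not redistributable, so
the generator is a first-class module: sequences are drawn i.i.d. per
position (uniform base composition by default), and the level of
sequence *i* is

$$\mathrm{level}_i = \mathrm{clip}\!\left(\mu_0 - \sum_w \beta_w\,
\mathrm{count}_w(\mathrm{seq}_i) + \varepsilon_i,\ 0,\ 1\right),
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

with overlapping motif counts, clipping applied after noise (boundary
pile-up at 0/1 is accepted and visible at large σ), and labels from the
0.5 cutoff. Defaults: µ0 = 0.5, β(UCC) = +0.15, β(GAG) = −0.15 (positive
β lowers the remaining level), σ = 0.1, n as requested. The planted
motifs mirror the strongest potency-increasing and potency-decreasing
trinucleotide composition features reported for real compilations, so
recovery runs are directly interpretable. `null_dataset()` draws
motif-free sequences with independent coin-flip labels for null checks
of importance, MCC and AUC; it carries no levels, because a level
consistent with a coin-flip label would be fiction.

This linear-in-counts model is a test harness, not a biological claim:
it emulates the statistical structure the method assumes — composition
features carrying the signal — and omits position-specific effects,
duplex thermodynamics, measurement-replicate structure and the
correlated noise of real screens. Passing recovery tests therefore
demonstrates that the machinery finds planted composition signal at
realistic sizes, not that it will attain any particular accuracy on
laboratory data.

One property of the defaults deserves emphasis. With µ0 exactly at the
0.5 cutoff, every motif-free sequence (about 58% of instances under the
uniform composition) gets its label from the sign of pure Gaussian
noise. No classifier can beat the Bayes score on this model, so pooled
AUC under the default scenario plateaus in the mid-0.7s regardless of
sample size or learner — the package's end-to-end tests reflect exactly
that: motif recovery is essentially certain while absolute AUC stays
moderate. Scenarios with µ0 displaced from the cutoff and small σ (e.g.
µ0 = 0.58, β(UCC) = 0.2, σ = 0.03) are separable nearly perfectly and
are what the test suite uses when it needs a high-AUC regime.

## Problem sizes and numerical choices

The full protocol (B = 1000 per forest, ten forests) is the default for
analyses. The test suite and the end-to-end recovery checks run the same
protocol at B = 200 with n = 400 (and n = 200 for single-forest
properties), sizes chosen so the whole suite exercises every stage —
including ten complete consensus-selection runs — in well under a
minute of forest time while leaving importance rankings stable across
seeds. Minimum accepted Gini decrease is 1e-12 (guarding float noise);
composition groups are validated to sum to 1 within 1e-12; the
threshold-sweep/rank AUC identity is asserted to 1e-10; SVM decision
values reproduce libsvm's to 1e-8.

## Known limitations

* The built-in folding backend counts pairs; it is not a Turner-energy
  model, and no siRNA:target duplex thermodynamics are computed.
* No probability calibration, multi-class support or regression-mode
  efficacy prediction; the SVM is a binary classifier whose continuous
  output is used only for ROC construction and efficacy correlation.
* Default (non-nested) evaluation reproduces the reference protocol's
  selection-before-CV order and thus its optimistic bias; use
  `nested = TRUE` when unbiased estimates matter.
* Replicate efficacy measurements per siRNA are assumed to have been
  merged upstream; the data model holds one level per record.
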