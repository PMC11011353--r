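---
title: "Iterative random-forest panel discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative random-forest panel discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the statistical machinery behind panelforest,
the assumptions it rests on, the parameters that matter, and the design
decisions taken where the procedure left room for choice. It states no
empirical result beyond what the package's own test suite and
acceptance script compute.

## The problem

Multiplexed isobaric-label (TMT) proteomics of a clinical cohort
typically yields a wide matrix: thousands of quantified protein groups
over a few dozen samples spread across several labeling batches, each
batch carrying one pooled internal-standard (IS) channel. The goal here
is a *compact, stable* panel of proteins that separates several disease
subtypes at once — a multiclass problem in the n ≪ p regime, where
single-split feature selection is notoriously irreproducible.

## Preprocessing chain

The chain is deliberately minimal and order-enforced (each stage checks
a scale flag and refuses out-of-order input):

1. **Filtering.** Contaminant-flagged proteins and proteins with a
   missing value in *any* channel (IS included) are removed. We chose
   the "missing in any" reading over "missing in all" because the
   pipeline performs no imputation, and trees downstream need complete
   cases; the policy is a `missing_policy` argument for users who want
   the laxer variant.
2. **log2 transform** of the strictly positive reporter-style
   intensities.
3. **Internal-standard standardization.** For each protein, each
   sample's log2 value minus the log2 value of its batch's IS channel.
   A batch effect that is multiplicative on the raw scale is an
   additive log2 offset shared by all channels of the batch, IS
   included, so the subtraction removes it *exactly* — the test suite
   asserts bit-level cancellation of injected offsets. IS columns are
   consumed here and never reach later stages.
4. **Median normalization.** Each sample column is shifted additively
   so all column medians equal the grand median of the pre-shift
   medians. The target constant is irrelevant to the tree ensembles
   downstream (they are invariant to per-feature monotone shifts
   applied uniformly across samples), but fixing it makes runs
   reproducible to the byte.

## Differential testing

Per protein: one-way fixed-effects ANOVA across all classes, and a
two-sided Welch *t*-test of control versus all cases pooled. Welch was
preferred over the pooled-variance test because the two sides are
heavily unbalanced (7 versus 33 in the emulated design). Multiplicity
is handled with Benjamini–Hochberg step-up adjustment, the proteomics
default, exposed as `adjust_pvalues()` (delegating to
`stats::p.adjust`). Proteins constant across all samples are reported
with p = 1 rather than dropped, so output rows always align with input
proteins.

## The ranking algorithm

`rank_features()` runs `n_outer_rounds` (default 30) rounds. Each
round restores the full feature set and repeats until a single feature
survives:

* fit a random forest (default 500 trees, ~√p candidate features per
  split, impurity importance) on the surviving features and add each
  survivor's importance to its running total;
* build a *shadow* copy of every survivor by permuting its values
  across samples, fit a second forest on survivors + shadows, and
  record a hit (1) for every survivor whose importance strictly
  exceeds its own shadow's — ties count 0;
* eliminate the least important `drop_fraction` (default 0.2, at least
  one feature; ties broken deterministically by protein id), recording
  a retention 1/0 for every feature, the eliminated ones continuing to
  collect zeros for the rest of the round.

Features accumulate importance and shadow hits only while retained, so
strong features — which survive deep into every round — accrue both
more importance and more shadow trials. The final table is sorted by
cumulative importance (ties: shadow hits, then id) and each feature
receives an exact binomial upper-tail p-value on its accumulated
shadow hits at null rate 1/2, the rate implied by exchangeability of a
feature and its shadow *in a single, selection-free comparison*.

Design choices worth recording:

* **Per-feature shadows, not max-of-shadows.** Each original is
  compared against its own permuted copy, which differs from
  Boruta-style selection against the best shadow; the tie rule
  (strictly greater wins) is fixed and tested.
* **Elimination fraction 0.2** follows the recursive-elimination
  scheme of Díaz-Uriarte & Álvarez de Andrés for microarray data;
  it is configurable.
* **Impurity importance** is the default (the classical R random
  forest default); permutation importance is available via
  `importance_kind`.
* **Two separate forest fits per inner step** — one plain, one
  shadow-augmented — exactly as the procedure prescribes, despite the
  cost; the ensemble size stays constant as features are eliminated.
* **Seeding.** A master seed spawns order-stable substreams per
  (round, inner step, fit), so any execution order reproduces the same
  tables.

### A calibration caveat that users should understand

The binomial p-value on accumulated shadow hits is a *ranking
heuristic*, not a calibrated test. After the first elimination, the
surviving features are selected — on the same data — for high
importance, and such survivors beat a freshly permuted shadow more
than half the time even when no feature carries signal. Accumulating
those selection-biased trials makes the p-values collapse toward zero
for whichever features happen to survive longest, including pure-noise
features on label-permuted data. The package's acceptance suite
documents this directly: in the selection-free setting (independent
shadow comparisons over the full feature set) hit rates sit inside
[0.45, 0.55] as exchangeability predicts, while under the full
iterative algorithm label-permuted data still produce features with
vanishing adjusted p-values. The same mechanism — the *same* lucky
features recur across partitions that share ~70% of their samples —
makes the stability-selection binomial null (below) anti-conservative
on null data. Interpret both p-values as ordering devices, trust the
planted-marker recovery and held-out classification results, and do
not read the p-values as false-positive guarantees.

## Stability selection

`run_stability()` draws `B` (default 100) stratified partitions; per
class, ⌈0.7·n⌉ samples go to training, capped at n−1 so every class
keeps a test sample (with class sizes 12/7/7/7/7 this gives the exact
29/11 split). The ranking runs on each training subset; the top k
(default 20) proteins per partition are tallied. Under the null that
every protein is equally likely to occupy a top-k slot, a protein's
hit count is Binomial(B, p̂) with p̂ = (k·B)/(P·B) = k/P; hits are
tested with the exact upper tail and BH-adjusted over the union of
proteins that ever entered a top-k (matching the universe the
procedure defines; adjusting over all P is a configuration choice).
`select_panel()` keeps the k most significant at `alpha` = 0.05,
ordered by adjusted p, hit count, then id. Per-partition seeds are
substreams of the master seed indexed by partition, so partitions are
reproducible and order-stable.

## Classifier benchmark

`train_classifiers()` tunes seven families by leave-one-out
cross-validated accuracy over small fixed grids, then refits on the
full training set. The grids (neighbors ∈ {3,5,7}; tree depth ∈
{2,4,6}; SVM cost ∈ {1,10,100} with RBF widths from both the
median-pairwise-distance heuristic and the 1/p default; ridge
multinomial λ ∈ {0.01,0.1,1}; two mtry values for the forest) are
minimal on purpose — with ~29 training samples anything finer is
noise. Every model exposes class probabilities; for the SVM these are
pairwise-coupling (Platt-style) estimates, an approximation noted
here because on very small training sets they can disagree with the
decision rule. Evaluation reports accuracy, Cohen's kappa (with the
degenerate all-mass-in-one-marginal case defined as 1 for perfect
agreement, else 0), one-vs-rest AUC per class by the Wilcoxon rank
statistic (ties = 1/2; classes lacking positives or negatives are
excluded from the macro mean with a warning), and the full confusion
matrix. `final_model_importance()` fits one random forest on all
samples and reports unscaled permutation importance, overall and per
class (accuracy decrease on each class's samples separately — the
standard per-class permutation importance). `mds_embedding()` is
classical (Torgerson) MDS on Euclidean distances, 3 dimensions by
default.

## The synthetic-data generator

`generate_dataset()` is first-class, tested code, and its defaults
*are* the emulated study conditions: five classes of 12/7/7/7/7
samples, 4 batches dealt round-robin over class-interleaved samples
(batch sizes differ by at most one), ~1000 proteins with per-protein
baseline log2 abundance N(20, 2), per-protein-per-batch log2 offsets
of sd 0.5 (multiplicative batch effects), cell-level log2 noise of sd
0.3, 30 planted markers shifted by 2 log2 units in their class
(classes assigned round-robin so each class has markers), 0.5%
missing cells completely at random, and 2% contaminant flags. The IS
channel is the per-batch geometric mean of that batch's samples — a
per-batch pool rather than the all-sample pool a lab would prepare,
so each batch is self-contained; for a batch-constant effect the two
choices cancel identically. Batch offsets are drawn as standard
normals and *scaled* by `batch_sd_log2`, so switching batch effects
on or off consumes the same random stream — this is what lets the
tests assert exact batch-effect cancellation at a fixed seed.

What the generator does **not** emulate: peptide-level roll-up, ratio
compression, isotopic impurity, intensity-dependent missingness
(missingness is MCAR because the pipeline's only policy is removal),
or correlated protein modules. Passing tests therefore demonstrate
algorithmic correctness and recovery of planted univariate shifts,
not performance on real cholestatic liver proteomes.

## Problem sizes used by the tests

The acceptance suite runs the stability stage at 500 proteins, 30
planted markers, B = 20 partitions and 5 outer rounds — a scale chosen
so the full suite completes in a few minutes on one CPU while leaving
the per-partition sample arithmetic (29/11) and all per-stage
contracts identical to the full-scale settings (100 partitions, 30
rounds) that remain the package defaults. Null-calibration checks use
100-tree forests; tree count affects importance noise, not the
selection bias discussed above. Degenerate inputs are handled
explicitly: constant proteins (p = 1), empty significant sets (empty
panel plus warning), classes missing from a test fold (AUC excluded
with warning), and every error message names the offending protein,
sample or batch.

## Known limitations

* The binomial p-values (ranking and stability) are anti-conservative
  under selection, as discussed; they order features well but do not
  control error rates.
* LOOCV tuning accuracy on ~29 samples has high variance; the chosen
  hyperparameters should be read as adequate, not optimal.
* The IS-standardization model assumes batch effects are
  multiplicative and channel-shared; intensity-dependent or
  protein-specific-nonlinear batch distortions are out of scope.
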