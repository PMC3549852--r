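---
title: "Meta-prediction of protein stability changes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-prediction of protein stability changes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabmeta)
```

## The problem

A single amino-acid substitution can stabilize or destabilize a folded
protein; the standard thermodynamic summary is ddG, the difference in folding
free-energy change between mutant and wild type (kcal/mol). Throughout this
package ddG > 0 means stabilizing — the convention shared by I-Mutant2.0 and
AUTO-MUTE; PoPMuSiC-derived tables use the opposite sign and are negated on
ingestion (`harmonize_sign()`).

Many public predictors call the *direction* of the change, and they
frequently disagree. stabmeta implements a stacked meta-predictor: the
categorical calls of seven element predictor models (I-Mutant_PDB,
I-Mutant_SEQ, AUTO-MUTE_RF, AUTO-MUTE_SVM, MUPRO_SVM, PoPMuSiC2.0, CUPSAT),
together with the local sequence context of the mutated site, are encoded
into a binary feature vector on which an RBF-kernel support vector machine
learns to call stabilizing vs destabilizing. A majority-voting baseline and a
support vector regressor for the ddG value itself are included, as are
stratified evaluations by secondary structure, relative solvent
accessibility, protein superfamily, and experimental pH/temperature.

The original element predictors were web services that no longer answer
queries. They sit behind a backend seam (`query_predictions()`): archived
outputs are served from a file cache (`cache_backend()`), and a simulator
(`simulator_backend()` / `simulate_predictions()`) generates synthetic calls
with configurable operating characteristics, so every stage of the pipeline
is exercisable offline. Re-implementing the element predictors themselves is
out of scope; their outputs are consumed, never recomputed.

## Dataset curation

`compile_mutations()` runs the curation pipeline in a fixed order:

1. **Sign harmonization.** Sources tagged with the PoPMuSiC convention have
   ddG negated; the operation is an involution, so applying it twice is the
   identity.
2. **Deduplication.** The mutation key is (PDB id, chain, position, wild-type,
   mutant). Replicate measurements differing only in pH/temperature are
   duplicates under this key. The *first record in input order* is kept —
   a deterministic, order-stable rule; replicates are dropped, not averaged,
   because averaging would fabricate a measurement at an undefined condition.
3. **Overlap removal.** When two datasets are later merged, records of the
   second whose key appears in the first are removed so the merged training
   set is unbiased. The chain is ignored in this comparison whenever either
   side lacks it, since older tables often omit chain identifiers.
4. **Labelling.** ddG > 0 is `POSITIVE` (stabilizing), ddG < 0 `NEGATIVE`.
   The strict inequalities leave ddG == 0 undefined; such records are
   excluded with a logged `"unlabeled"` reject rather than silently assigned.
5. **Position correction.** Tables sometimes number residues by the
   structure's absolute numbering while the FASTA is relative (a missing
   initiator Met is the classic case). `correct_position_offset()` finds the
   single shift reconciling *all* of a chain's records with its sequence,
   preferring 0, then the smallest |shift| with ties to the negative side,
   and fails loudly when no shift fits.
6. **Window extraction.** An odd-width window (default 11) centered on the
   mutated site; positions beyond a terminus are padded with `-`, which is a
   first-class 21st symbol of the alphabet, not a missing value.
7. **Strata annotation.** DSSP-style secondary-structure symbols collapse to
   helix (H/G/I), sheet (E/B), other (T/S/C). Percent RSA is classed as
   buried/partial/exposed. The printed class ranges overlap at their
   boundaries (20% and 50%), so half-open bins are adopted: [0,20) = B,
   [20,50) = P, [50,100] = E. pH and temperature bins for the condition grid
   are lower-inclusive: pH <= 6, (6,8], > 8; temperature <= 37, (37,65], > 65 °C.

Every step appends to a provenance list, and `dataset_manifest()` summarizes
record/protein/class counts, so dataset lineage (and any count discrepancy
against an external description of the same data) stays visible rather than
hidden.

## Feature encoding

Two schemes are concatenated (`encode_features()`):

* **Sequence scheme** — each window position is a 21-bit one-hot (20 amino
  acids in fixed alphabetical order, then `-`), plus one extra block for the
  mutant residue: `21 × (w + 1)` bits, i.e. 252 + 21 = 273 total with the
  seven predictor blocks at w = 11.
* **Website-result scheme** — one 3-bit block per element predictor in a
  fixed canonical order: destabilizing `1-0-0`, null `0-1-0`, stabilizing
  `0-0-1`. A *null* prediction (server unreachable, mutation rejected,
  missing cache entry) is an explicit third state, not an imputed value.

Four modes are exposed: `seq_ws` (273 features at w = 11), `ws_only` (21),
`seq_ws_no_amrf` (270; drops AUTO-MUTE_RF, historically the strongest but
slowest element predictor), and `istable_seq` (258; sequence scheme plus only
the two sequence-input predictors, for queries with no known structure).

The alphabet order and the predictor block order are not dictated by the
method itself, so they are frozen here (alphabetical with `-` last; the
canonical listing order) and embedded in a layout table that every encoder
emits and every trained model checks, making encodings losslessly decodable
(`decode_features()`) and models refusable on layout mismatch. Features are
0/1 and deliberately unscaled. Matrices export densely (TSV) and as sparse
LIBSVM-style `index:value` lines with +1/−1 labels.

## The SVM integrator

`train_classifier()` fits a C-classification SVM (RBF kernel) through
e1071/LIBSVM with the integrator's fixed hyperparameters γ = 0.03125 and
C = 2; no class weighting and no probability calibration are applied, and
the decision threshold is 0 (the decision value is reported, oriented so
positive favors stabilizing). The known sensitivity/specificity asymmetry of
element predictors on curated data — destabilizing calls are far more
reliable than stabilizing ones — is reproduced, not corrected.

`cross_validate()` implements 5-fold cross-validation with label-stratified
random folds assigned by seed. Whether the original protocol stratified by
label or split by protein is not recorded anywhere; per-record stratified
folds match the era's common practice and the per-mutation bookkeeping of the
published tables, and they are the default here. Note per-record splitting
lets homologous sites of one protein fall on both sides of a fold boundary,
which flatters absolute numbers; `superfamily_cv()` and the `folds` argument
allow stricter protocols. Fold metrics are **pooled** (TP/FP/FN/TN summed
across folds, metrics computed once) rather than averaged per fold — pooling
reproduces whole-dataset tables exactly and avoids per-fold weighting
ambiguity.

`window_size_sweep()` re-extracts windows at each size in {7, …, 19} and
reuses a single fold assignment across sizes (verifiable via the exposed fold
hash) so that only the window width varies.

### Metrics

Accuracy, sensitivity, specificity and the Matthews correlation coefficient
from pooled confusion counts. MCC with a zero marginal is mathematically
undefined; it is reported as 0 with a `mcc_degenerate` flag — 0 is the
"random prediction" value, and the flag keeps the convention auditable. Sn
(Sp) is reported absent when the evaluation set has no positives (negatives).

### Majority voting baseline

`majority_vote()` drops null calls and takes the larger camp. Ties (and the
all-null case) go to `NEGATIVE`, destabilizing being the majority class in
every curated stability dataset, and carry an explicit tie flag: how the
historical baseline handled ties is unreported, so the choice is declared
rather than implied.

### ddG regression

`train_ddg_regressor()` fits an ε-insensitive RBF SVR (ε = 0.1 by default,
γ and C shared with the classifier — the regression hyperparameters were
never published, so the classifier's are reused and all three are
overridable) on the ddG estimates of the four structure-based predictors.
The sequence one-hots can be appended (`include_sequence = TRUE`) but are off
by default: the regression's information lives in the four ddG inputs, and
252 extra binary dimensions dominate the RBF distance to no benefit. With
sequence-only input exactly one element predictor emits a ddG value, so no
regression is fitted: the model passes the I-Mutant_SEQ estimate through
verbatim. `ddg_regression_cv()` reports Pearson r and RMSE both pooled
held-out and on the training fit, since published correlation plots of this
kind rarely state which of the two they show.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of curated
single-point-mutation sets: a configurable stabilizing fraction (default 1/3 —
curated sets run roughly 2:1 destabilizing:stabilizing), |ddG| exponential
with mean `ddg_scale` = 1 kcal/mol signed by the label (so only the sign
carries label information, matching the classification task), uniform-random
protein sequences, unique mutation keys by construction, and
SS/RSA/superfamily/pH/temperature strata drawn from configurable weights.
`simulate_predictions()` draws each predictor's call conditionally
independently given the truth: null with `null_rate`, otherwise correct with
probability `sensitivity` (stabilizing records) or `specificity`
(destabilizing records). `predictor_profiles()` exposes the seven published
(Sn, Sp) operating points on each of the three benchmark datasets as
ready-made profiles; the per-predictor null rate was never published, so a
small default (0.02) models the occasional unanswered query. ddG-emitting
predictors report the true |ddG| plus Gaussian noise (SD 0.8 kcal/mol),
signed consistently with their own call.

What the simulator deliberately does **not** reproduce: real sequences
(windows carry no label signal, so in simulation the sequence scheme is pure
noise and `seq_ws` ≈ `ws_only`); inter-predictor correlation (real
predictors share training data and physics and err together — an independence
assumption makes expectations analyzable but *overstates* the ensemble gain
of stacking, so simulated meta-vs-element margins are upper bounds);
thermodynamic realism of ddG beyond sign and scale; and the sign-consistency
coupling between a simulated predictor's ddG estimate and its (often wrong)
call makes the simulated regression inputs noisier than archived server
outputs. Passing tests therefore demonstrate the machinery — encodings,
protocol, metrics, ordering of methods — not real-data accuracy levels.

## Problem sizes and numerical choices

The test suite runs its ensemble checks on simulated datasets of 400–3000
records (profile-recovery and integrator-vs-element comparisons use n = 3000,
where binomial error on Sn/Sp is about ±0.015); the acceptance script
simulates 3131 records to mirror the merged benchmark's size. SVM fits are
deterministic given data order and configuration; all stochastic steps
(generator, predictor draws, fold assignment) are seed-controlled and
byte-reproducible. Counts in metrics are accumulated as doubles before the
MCC product, which otherwise overflows 32-bit integers near n = 10^5.

## Known limitations

* Simulation-based evaluation cannot validate against the historical web
  servers' actual outputs; the cache backend accepts archived predictions
  when they exist.
* Per-record CV leaks protein-level homology (see above).
* Only the SVM combiner ships; alternative combiners (random forest, neural
  network, Bayesian network, RBF network) are reachable through the same
  feature encodings but are not implemented.
* Secondary structure and RSA are consumed as annotations; they are never
  computed from coordinates here.
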