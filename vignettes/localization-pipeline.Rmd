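---
title: "Predicting lncRNA subcellular localization with stacked ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA subcellular localization with stacked ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whether a long non-coding RNA (lncRNA) acts in the nucleus (chromatin
scaffolding, transcriptional regulation) or the cytoplasm (miRNA sponging,
translational control) is largely determined by where the cell puts it.
`lncstack` predicts that binary localization — cytoplasm (positive class)
versus nucleus (negative class) — from the transcript sequence alone, using
a two-layer stacked ensemble over a deliberately broad, formula-defined
feature space.

The pipeline has four stages:

1. **Encoding.** Five nucleotide descriptor families and three amino-acid
   descriptor families are computed per transcript and fused column-wise.
2. **Consensus feature selection.** Seven selection algorithms each produce
   a boolean mask; features kept by at least four of the seven enter the
   model space.
3. **Automatic base-model selection.** Eleven heterogeneous learners are
   trained; their out-of-fold probability outputs form an n-by-11 matrix
   `Z`, and a Boruta shadow-feature screen on `Z` decides which learners
   carry task-relevant signal.
4. **Stacking.** The selected learners' out-of-fold probabilities train a
   logistic-regression meta-learner
   `p = sigmoid(beta0 + sum_k beta_k * h_k(x))`; base learners are then
   refit on all data for deployment.

## Feature encoders

All encoders operate on the DNA alphabet; RNA input is accepted and `U` is
mapped to `T` on read. Records containing other ambiguity codes are dropped
by default (every formula below assumes the 4-letter alphabet); a nonzero
tolerance strips the ambiguous characters instead.

**Nucleotide side** (1,660 columns):

| encoder | dim | definition |
|---|---|---|
| cumulative skew | 2 | `(G−C)/L` and `(A−T)/L`, the final value of the cumulative skew curves |
| CTD | 30 | 4 base compositions, 6 bidirectional transition frequencies over `N−1` adjacent pairs, and 5 occurrence-quantile positions (first/25/50/75/100%) per base, divided by `N` |
| PseKNC, k = 2..5 | 19/67/259/1027 | k-mer frequencies plus `lambda = 3` correlation tiers `theta_j`, the mean squared difference of standardized dinucleotide physicochemical indices at lag `j`, weighted by `w = 0.1` and jointly normalized to sum 1 |
| 4-mer | 256 | word frequencies over sliding windows |

Two conventions deserve a note. The cumulative-skew formulas define a
per-position curve, but the descriptor is fixed at two dimensions, so the
final-position value (the whole-sequence skew) is emitted — the only scalar
the cumulative curve converges to. And the literal k-mer definition divides
by the sequence length `L`; that breaks the sum-to-one property, so the
default divides by the window count `L − k + 1`, with
`kmer.denominator = length` available to reproduce the literal formula.

The PseKNC correlation tiers need per-dinucleotide physicochemical values
(rise, roll, shift, slide, tilt, twist). The bundled table
(`inst/extdata/dinuc_indices_synthetic.tsv`) contains constructed stand-in
values, as the filename indicates: indices are standardized to zero mean and
unit variance over the 16 dinucleotides before use, every published helical
parameter table produces the same feature dimensions, and the table is
user-replaceable (`pseknc.indices_path`). Swapping tables changes PseKNC
values, never shapes, and all correctness tests use explicit toy tables.

**Amino-acid side** (10,439 columns). Each transcript is scanned on the
forward strand for stop-terminated ORFs starting at `ATG` with
`minlen = 30` nt (configurable); the two highest-rated ORFs are kept. The
rating function defaults to ORF length — the standard ORF-calling heuristic
— and is replaceable (a Kozak-context score would slot in here). Their
translated peptides are concatenated in descending-score order, and the
amino-acid encoders run once per transcript on this combined peptide; with
the published block widths (39 + 2400 + 8000) this is what yields the
12,099-column fused space. When no ORF exists the combined peptide is empty
and every amino-acid encoder emits its all-zero vector at full width, so
downstream matrices keep their shape.

| encoder | dim | definition |
|---|---|---|
| CTDT | 39 | for each of 13 property-based 3-group partitions of the residues, the three cross-group transition frequencies over `N−1` adjacent pairs |
| CKSAAP | 2400 | for each gap `g = 0..5`, frequencies of the 400 ordered residue pairs `(r_i, r_{i+g+1})`, normalized per gap by `L−g−1` |
| TPC | 8000 | tripeptide counts at index `i1*400 + i2*20 + i3`, normalized by the total |

TPC nominally standardizes peptides to 300 residues. Padding with any real
residue would fabricate tripeptides, so standardization is implemented as
truncation only; shorter peptides are counted as-is and the normalization
absorbs length.

## Consensus feature selection

The seven selectors and their defaults:

* **variance threshold** (`> 0`): drops constants;
* **F-test**: two-group ANOVA, keep at `p < 0.05`; a perfect separator
  (zero within-group variance, positive between-group variance) is kept;
* **RFE**: random-forest importance, dropping 10% of remaining features per
  round down to `ceiling(sqrt(p))` columns — the target scales with
  dimension like the usual random-forest `mtry` heuristic, keeping the
  wrapper aggressive in very wide spaces;
* **model importance**: random-forest impurity importance normalized to sum
  one, cutoff `1.5e-6` (the published operating point);
* **L1**: lasso-penalized logistic regression on standardized columns,
  penalty chosen by seeded cross-validation under the one-standard-error
  rule (the CV-minimum penalty is known to overselect), keep nonzero
  weights;
* **mutual information**: equal-frequency discretization (8 bins), keep
  strictly positive estimates. The Miller-Madow bias-corrected plug-in
  estimator is used: the raw plug-in estimate is almost surely positive even
  for independent features, which would reduce this selector to a constant
  vote; subtracting the expected bias `(B-1)(C-1)/(2n)` restores an
  informative (if still lenient) vote while keeping constant features at
  exactly zero;
* **Boruta**: per iteration, every active column is shuffled into a shadow
  copy, a random forest is fit on real plus shadow columns, and a feature
  scores a hit when its importance exceeds the maximum shadow importance.
  Accumulated hits feed two one-sided binomial tests at
  Bonferroni-corrected `alpha = 0.05` (corrected by the initial feature
  count, the classic Boruta convention); rejected features leave the model,
  and anything undecided at `max_iter = 100` is rejected conservatively.

A feature enters the final space with more than 4 of 7 votes (i.e. at
least 5; `selection.threshold` configures this). The method's defining
formula states the strict inequality while the surrounding prose says "at
least four"; the strict reading is used here because it is the only one
consistent with how the selector family behaves. The variance threshold
(`> 0`) and the model-importance cutoff (1.5e-6 on importances normalized
to sum one) pass essentially every non-constant feature in a wide matrix,
and the MI vote passes any feature whose chance association with the labels
is mild — so three votes are nearly free, an inclusive "at least four"
rule would reduce the consensus to a union of the remaining weak selectors,
and the advertised behavior of the vote (keeping planted signal while
excluding all but a few percent of noise features) holds only under the
strict rule. If the vote selects nothing, the threshold falls back to the
maximum observed vote count (logged) so a run always proceeds.

## Model pool, automatic selection, stacking

The pool holds eleven members: `lr`, `knn`, `svm`, `rf`, `adaboost`, `gb`,
`extratrees`, `dtree`, `xgb`, `lgbm_style`, `catboost_style`. Two notes:

* AdaBoost is implemented directly (SAMME over decision stumps with the
  logistic margin-to-probability map), since no installed package provides
  it.
* `lgbm_style` and `catboost_style` are gradient-boosting configurations
  patterned on the characteristic growth strategies of the LightGBM
  (leaf-wise/lossguide growth, histogram splits) and CatBoost (shallow
  symmetric trees, low learning rate, feature subsampling) libraries,
  realized through xgboost. They keep the pool heterogeneous along the same
  axes while staying within this package's dependency set.

Grid tuning (3-fold CV maximizing MCC) is available but off by default: the
bundled grids are tiny (1-3 points), and the default parameters are the
grid's first points. The output matrix `Z` is built from **out-of-fold**
probabilities under shared stratified 5-fold splits, not resubstitution
outputs: a memorizing learner would otherwise look perfect to the
meta-stage, and the leakage-guard test (permuted labels must give AUC about
0.5) enforces this choice. Boruta on `Z` then names the selected members;
if it confirms none (a possibility the method description leaves open), the
single member with the best out-of-fold MCC is used.

The meta-learner is an unpenalized binomial GLM on the selected members'
out-of-fold probabilities — one column per member, since the negative-class
probability is redundant in a binary task. Predicted probabilities are
clamped to the open unit interval; the decision threshold defaults to 0.5
and is configurable.

## Synthetic data: what it emulates, what it does not

`synthetic_spec()` generates labelled transcripts with two independent,
class-dependent signal channels, mirroring the pipeline's two encoder
families:

* a **nucleotide channel**: class-specific base composition
  (A/T-rich cytoplasmic 0.28/0.22 vs G/C-rich nuclear 0.26/0.24) plus two
  marker 4-mers planted at 1 copy/kb in nuclear and 4 copies/kb in
  cytoplasmic records;
* an **amino-acid channel**: with probability 0.9 an in-frame 80-residue
  ORF is inserted whose residue distribution is biased towards K/R/L
  (cytoplasm) or S/G/P (nucleus).

Lengths are log-uniform on 200-3000 nt, 300 records per class. These
defaults were chosen once as a realistic-but-learnable operating point: the
compositional difference is about 3 standard errors per kilobase-scale
transcript, strong enough that a correctly assembled pipeline separates the
classes clearly and a broken stage shows up as a measurable drop.
`signal = FALSE` copies the positive-class settings onto the negative
class, giving an exchangeable null for calibration checks.

The generator emulates *composition, motif and ORF structure only*. Real
lncRNA localization signal involves splicing-derived elements, repeat
content, secondary structure and cell-type dependence, none of which are
modelled. Passing recovery tests therefore demonstrates that the pipeline's
machinery works — encoders see their channels, selection keeps informative
columns, stacking combines learners without leakage — not that the learned
models transfer to biological data; for that, train on real labelled sets.

## Numerical conventions and degenerate inputs

* Metric denominators of zero yield 0 with a warning (including the MCC).
* AUC integrates TPR over FPR trapezoidally with tied scores grouped, and
  equals the normalized Mann-Whitney statistic exactly; AP is the
  step-wise, non-interpolated precision-recall integral.
* ORF ties (equal rating) break by smaller start, then smaller frame.
* CKSAAP gap blocks with no admissible pairs are all-zero rather than
  undefined; CTDT and TPC behave likewise below their window sizes.
* Sequences shorter than the configured encoder minimum (5 nt with the
  default PseKNC settings) get per-record `NA` predictions with a note; a
  run never aborts on one short record.
* All stochastic stages (forests, boosting, fold assignment, Boruta
  shuffles) derive per-call seeds from the single run seed; training twice
  with the same seed gives identical models, and prediction is
  deterministic given a model.

## Problem sizes used by the test suite

The packaged recovery experiments run at the generator's default study
conditions (600 records, seed 7) for the end-to-end checks, with smaller
deterministic fixtures (tens of records, reduced encoder sets) for the
unit-level contracts. Boruta's operating characteristics are measured over
50 seeded replicates at n = 200 with one planted signal among 20 noise
features; the leakage guard averages member-wise out-of-fold AUC over 5
label permutations at n = 200. These sizes were picked so the full suite
stays desk-scale while keeping the binomial/normal error bars of each check
well inside its asserted tolerance.

## Known limitations

* Only the forward strand is scanned for ORFs — inputs are transcripts, not
  genomic DNA — and only the standard genetic code is supported.
* The ORF rating is length; coding-potential scores (CPAT-style) are out of
  scope but pluggable via the `rating` argument.
* Binary localization only; multi-compartment prediction and cell-line
  conditional models are out of scope.
* The bundled dinucleotide index table is a constructed stand-in (see
  above); users wanting a specific published parameter set should supply it
  via `pseknc.indices_path`.

## A worked run

```{r example}
library(lncstack)

spec <- synthetic_spec(n_pos = 100, n_neg = 100)
gen <- generate_synthetic(spec, seed = 7)

model <- train_localizer(gen$dataset, seed = 7)

test <- generate_synthetic(spec, seed = 8)
preds <- predict(model, test$dataset)
evaluate_predictions(test$dataset$label, preds$prob)[c("auc", "mcc")]
```

The same workflow is available from the shell via the installed
`exec/lncstack` script (`simulate`, `encode`, `select`, `train`, `predict`,
`evaluate` subcommands).
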