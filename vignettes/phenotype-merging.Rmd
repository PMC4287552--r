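---
title: "Comparing cell-phenotype classifiers and merging confusable phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cell-phenotype classifiers and merging confusable phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclass)
```

## The problem

High-content screens segment millions of cells from microscopy images and
describe each cell by hundreds of numeric features (geometry, Haralick
texture, Zernike moments).  A biologist labels a few thousand cells with
morphological phenotypes — metaphase, actin blebs, large spread cells, and
so on — and a classifier trained on those labels is used to annotate the
rest of the screen.  Two practical questions dominate this workflow:

1. **Which classifier?**  Training is iterative (label, train,
   cross-validate, inspect, label more), so evaluation speed matters as
   much as accuracy.
2. **Which phenotypes are really distinct?**  Expert catalogs often contain
   pairs of classes the features cannot separate.  Merging the most
   confused phenotypes and re-evaluating quantifies how much accuracy is
   bought by a coarser catalog.

`phenoclass` implements both analyses for four classification protocols
behind one fit/predict/posterior contract, together with the confidence
analyses that support them: repeated-CV consensus misclassification and
posterior-probability reject-option curves.

## Classification protocols

All protocols consume feature tables whose columns have been z-scored and
min–max rescaled to $[0,1]$ (`normalize_features()`).  Scaling parameters
are learned on training folds and applied to held-out folds; a
`global_scaling` flag reproduces the simpler whole-table scaling at the
cost of mild leakage.

* **Gentle boosting** (`gentle_boost`), one-vs-all.  The weak learner is a
  regression stump $f(x) = a\,\mathbf{1}[x_j > \theta] + b$.  Each round
  selects, by exhaustive search over every feature and every midpoint
  between consecutive sorted unique values, the stump minimizing the
  weighted squared error $\sum_i w_i (y_i - f(x_i))^2$, adds it to the
  additive score $F$, and reweights cells by $e^{-y_i f(x_i)}$.  The
  default is 50 rounds, the size commonly recommended for screening data.
  Ties in weighted error are broken toward the lower feature index and
  lower threshold, making the fit deterministic and equal to the
  brute-force oracle used in the tests.
* **Linear SVM** (`svm_linear`), one-vs-all, L2-regularized L2-loss.  Each
  binary problem minimizes the smooth squared-hinge primal
  $\tfrac12\|w\|^2 + C \sum_i \max(0, 1 - y_i w^\top \tilde x_i)^2$ (bias
  absorbed by feature augmentation) with a quasi-Newton solver and analytic
  gradient; the default grid for $C$ is $2^{-5},\dots,2^{6}$.
* **RBF SVM** (`svm_rbf`), one-vs-one with majority-vote decoding (libsvm
  back-end), default grids $C \in 2^{-1},\dots,2^{6}$ and
  $\gamma \in 2^{-5},\dots,2^{1}$.
* **LDA** (`lda_pinv`): class means, empirical priors and a pooled
  within-class covariance inverted with the Moore–Penrose pseudo-inverse,
  so feature tables with exactly linearly dependent columns (derived
  features) are handled without error.  On full-rank data the scores equal
  textbook LDA to $10^{-8}$.

SVM hyperparameters are selected by stratified 5-fold cross-validation over
the grids, ties resolved toward the smaller $C$ then the smaller $\gamma$.
Because it is ambiguous whether such selection should happen once or inside
every outer fold, `cross_validate()` defaults to the unbiased nested search
(`tune = "per_fold"`) and offers `tune = "once"` where the cheaper variant
is appropriate (it is the default in the pipeline runner, where dozens of
CV runs share one table).

## Evaluation

`cross_validate()` uses stratified $k$-fold assignment (default $k = 20$):
within every phenotype, cells are dealt round-robin into folds, so
per-phenotype fold sizes differ by at most one even under strong class
imbalance — e.g. a 34-cell phenotype splits over 20 folds as fourteen folds
of 2 and six folds of 1.  Predictions are pooled into a single confusion
matrix, and accuracy is the number of correctly classified cells divided by
the total number of cells (micro-averaged), rather than a mean of per-fold
accuracies; the two differ under imbalance and the pooled definition is the
one the accuracy/confusion contract enforces (`accuracy = trace/total`
exactly).

`subsample_experiment()` draws stratified subsamples at fractions
$1/2,\dots,1/16$ (per phenotype `round(fraction * count)` cells, minimum 1 —
the rounding that maps half of 563 to 282) and repeats each draw 50 times
by default, reporting mean ± sd accuracy per fraction.

## Merging confusable phenotypes

The merging analysis (`ladder_evaluation()`) proceeds exactly once per
data set:

1. run level-$K$ cross-validation for the classifier set and average the
   confusion matrices element-wise;
2. symmetrize by adding upper and lower triangles (diagonal kept as is);
3. divide each row by its row sum;
4. subtract from one (diagonal set to zero) to obtain a dissimilarity.

Row-normalizing a symmetric matrix breaks symmetry whenever row sums
differ, so the result is re-symmetrized by averaging with its transpose —
the smallest correction that satisfies the clustering input contract.
Whether the diagonal (correct classifications) should count in the row sums
is equally unstated in common practice; `phenoclass` keeps it by default
(frequently-correct phenotypes then look less confusable overall) and
offers `exclude_diagonal = TRUE`.

The dissimilarity is clustered with UPGMA (`upgma()`): merge the closest
pair, define cluster distances as unweighted means over member pairs, and
repeat.  Ties are broken toward the lexicographically smallest cluster-id
pair, making the ladder deterministic; on tie-free inputs it matches
`hclust(method = "average")` exactly (oracle-tested).  The ladder is then
walked from $K$ clusters down to 2 — never to 1, which would be vacuous —
relabeling cells by each level's map (merged phenotypes get hyphen-joined
names) and re-running cross-validation for *every* classifier with the same
fixed merging.

## Confidence analyses

**Consensus misclassification.**  `consensus_misclassified()` repeats
cross-validation `runs` times (default 100), varying only the fold seed,
and flags cells wrongly classified in at least `min_wrong` runs (default
80).  `overlap_fraction(A, B)` is $|A \cap B| / |A|$ — the fraction of one
classifier's consensus errors shared by another; it is an error (not zero)
when the reference set is empty.  Hyperparameters are tuned once on the
full table and reused across runs by default: the statistic concerns fold
randomness, and re-tuning inside each of 100 runs changes nothing
qualitatively while multiplying cost (a `retune_per_run` flag restores the
expensive variant).

**Reject option.**  Posterior probabilities come from Platt sigmoids
$p = 1/(1 + e^{As + B})$ fitted by regularized maximum likelihood (Platt's
smoothed targets) on decision scores.  Calibration scores are *cross-fitted*
(3-fold within the training fold) to avoid resubstitution optimism.  For
one-vs-all protocols the per-class sigmoid outputs are normalized to sum to
one; for the one-vs-one RBF SVM, per-pair sigmoids are combined by
pairwise coupling (the quadratic-program formulation solved as a linear
system, tiny negatives clipped).  Posterior rows sum to 1 within $10^{-9}$.
The coupled-posterior argmax can disagree with majority-vote decoding on
ambiguous cells; reference one-vs-one implementations show the same effect,
and the package tracks the agreement rate in its test suite rather than
forcing the two decodings to coincide.

`threshold_curve()` drops cells whose maximum posterior falls below a
threshold (inclusion uses $\ge t$, so $t = 0$ is the identity) and reports
coverage and accuracy per threshold over a default grid $0, 0.05, \dots,
0.95$.  The curve is truncated at `phenotype_exclusion_threshold()` — the
smallest threshold at which some phenotype retains no cells (the minimum
over phenotypes of the maximum of its cells' max-posteriors) — so apparent
accuracy gains can never come from silently dropping an entire phenotype.

## The synthetic generator

`generate_dataset()` emulates the structural properties of expert-labelled
screening tables that matter to these analyses, with known ground truth:

* **class imbalance** — per-phenotype counts are reproduced exactly (the
  bundled HT29/HeLa count tables are natural presets; the HT29 catalog has
  a 16:1 ratio between its largest and smallest phenotypes);
* **confusability** — each phenotype is a unit-variance spherical Gaussian;
  group representatives sit on scaled coordinate vertices
  `class_separation` apart, and each confusable partner is displaced from
  its representative by `(1 − overlap) × class_separation` along its own
  coordinate direction, so the planted pairs are the unique closest-pair
  structure and `planted_merge_order()` is the ground-truth merge sequence;
* **rank deficiency** — optional extra columns that are exact linear
  combinations of base columns with uniform(−1, 1) coefficients, mirroring
  screening tables whose features are derived from other features.

One seeded RNG stream is consumed in a documented order (cells
class-by-class, then dependent-column coefficients), so identical
configurations are bit-identical; reproducibility *across* edited
configurations is deliberately not promised.

The generator does **not** attempt realistic marginal feature
distributions, heavy tails, label noise, batch effects, or correlated
within-class covariance.  Tests passing on these tables therefore certify
the pipeline's mechanics (stratification, tuning, merging, calibration,
bookkeeping) and its directional behaviour, not performance on real
screening data.

## Numerical choices and degenerate inputs

* Constant feature columns normalize to 0 with a warning; held-out values
  are not clipped to $[0,1]$.
* Stump thresholds are midpoints between consecutive sorted unique values;
  features without two distinct values are skipped; if no feature admits a
  split, boosting stops early with the rounds fitted so far.
* The boosting exponential training loss is recorded per round and is
  non-increasing on all generated data (tested).
* Phenotypes smaller than $k$ leave some folds empty of that phenotype —
  allowed, as in practice with 20 folds and rare phenotypes.
* A phenotype never predicted correctly by any classifier still has a
  nonzero dissimilarity row sum whenever it has cells; a zero row sum (a
  phenotype absent from the evaluated cells) is an error naming the
  phenotype.
* Seeds derived internally (per fold, per repeat) stay below $2^{31}$.

## Problem sizes used in the test suite

The suite exercises the full pipeline at desk scale — hundreds to a few
thousand cells, 4–16 features, $K \le 14$ — chosen so the complete suite
and the reproduction script run in minutes on one CPU while leaving every
statistical check comfortably powered: oracle equivalences use 100 random
instances each, planted-hierarchy recovery uses 40 data sets of 720 cells,
and the directional properties (ladder monotonicity, subsampling decay,
reject-option gain) use 20 seeds with a one-standard-deviation tolerance.

## Limitations

* Joint boosting with stumps shared across phenotypes is out of scope; the
  one-vs-all gentle boosting implemented here is the non-sharing variant.
* Image segmentation and feature extraction are upstream of this package:
  it starts from feature tables.
* The merge ladder is an analysis device; the package draws no biological
  conclusions from phenotype similarity.
* LDA posteriors are its native Gaussian ones; no Platt calibration is
  applied on top.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n_phenotypes = 4, class_counts = c(40, 160, 80, 120), n_features = 8,
  class_separation = 4,
  confusable_pairs = list(list(pair = c(1, 2), overlap = 0.8)),
  seed = 11)

exp <- experiment_config(
  input = cfg,
  specs = list(classifier_spec("lda_pinv"),
               classifier_spec("svm_linear", C_grid = 1)),
  k = 10, seed = 11,
  consensus = list(runs = 20, min_wrong = 16),
  subsample = list(fractions = c(1/2, 1/4), repeats = 10),
  output_dir = "phenoclass_out")

bundle <- run_pipeline(exp)
bundle$ladder$accuracies
```
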