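---
title: "Screening acute suicidal ideation with graph isomorphism networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening acute suicidal ideation with graph isomorphism networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Acute suicidal ideation (SI) — having thought about suicide within the past
two weeks — is a rare (~1%) but critical screening target in young-adult
mental-health check-ups.  Conventional classifiers trained on such data
collapse onto the majority class: they report excellent specificity and
accuracy while missing most of the people the screen exists to find.
`ginscreen` implements a screening pipeline that addresses this with three
ingredients:

1. **a psychometric graph representation** — each subject becomes a small
   graph whose nodes are questionnaire items (PHQ-9 depression items, GAD-7
   anxiety items) and quartile-coded scale totals (state anxiety,
   resilience, self-esteem) plus binary clinico-demographic nodes, all
   sharing one sparse, signed correlation edge matrix;
2. **a graph isomorphism network (GIN) classifier** with per-layer
   sum-pooling and a concatenated readout;
3. **a class-imbalance ensemble** — three GINs trained on differently
   rebalanced data (under-sampling to 10 and 5 negatives per positive,
   SMOTE-NC over-sampling to 1:1), soft-voted by averaging their sigmoid
   scores.

A fourth component handles the partially observed diagnostic label: a GIN
trained on the subjects with a structured-interview major-depressive-episode
(MaDE) diagnosis pseudo-labels everyone else, and the (true or pseudo) MaDE
indicator becomes an input node of the SI models.

# The graph representation

## Node vocabulary and features

The SI model's vocabulary holds 19 ordinal nodes (9 PHQ items, 7 GAD items,
3 quartile-coded totals) and 4 binary nodes (lifetime suicide attempt, MaDE,
gender, institution type); the MaDE model drops the MaDE node (it is the
target) and lifetime SA, keeping gender and institution.  Every node carries
a 6-slot one-hot feature: slots 1–4 encode the ordinal level, slots 5–6
binary absence/presence.  The deliberately level-resolved encoding is what
makes the attention analyses possible: a gradient exists for every
(node, level) pair.

Scale totals are quartile-coded with cut points at the 25/50/75 empirical
percentiles (linear interpolation between order statistics, ties to the
lower level) of the *training partition only*, and applied unchanged to
validation and test data — distributional information must not leak out of
the training split.  The resilience and self-esteem totals are reversed
(their top raw quartile codes as level 1) so that higher levels mean higher
severity on every ordinal node.

## The shared edge matrix

Edges are pairwise correlations between the integer node codes on the
training partition; entries below the sparsity threshold (default 0.6) are
zeroed and the sign of retained entries is kept.  Spearman correlation is
the default — the nodes are ordinal codes — with Pearson available.  All
subjects share this one edge matrix; only node features differ between
subjects.  The diagonal is zero: the self-contribution enters through the
GIN's $(1+\epsilon)$ term, not through self-edges.

Whether aggregation should use the signed weight or its magnitude is not
determined by the problem; signed weights are the default and
`gin_config(binarize_edges = TRUE)` gives an unweighted variant.

# The GIN classifier

For node $v$ at layer $k$ with shared weighted adjacency $A$:

$$h_v^{(k)} = \mathrm{MLP}_k\!\Big((1+\epsilon_k)\,h_v^{(k-1)} +
  \sum_u A_{vu}\, h_u^{(k-1)}\Big)$$

Each MLP is two affine maps with batch normalization after each and a ReLU
between; $\epsilon_k$ is learnable (initialised at 0).  After every layer
the node features are sum-pooled into a per-layer graph feature
$p_G^{(k)} = \sum_v h_v^{(k)}$; the $K$ pooled vectors are concatenated and
a linear classifier maps the concatenation to a raw score $y$, reported
through a sigmoid.  Because all subjects share $A$, a minibatch is processed
with one $(V\times V)(V \times BC)$ multiply per layer, and cost is linear
in the edge count.

Batch normalization is not cosmetic here.  The aggregation multiplies
activations by a matrix whose rows sum to well above 1 on densely connected
nodes, so activations inflate multiplicatively with depth; without
normalization the under-sampled members train an order of magnitude worse.
Training uses batch statistics; prediction and input gradients use the
stored running statistics — at inference batch norm is then a fixed affine
map (folded directly into the adjacent weights), so per-subject outputs are
deterministic and permutation invariance holds exactly.

Training is minibatch Adam (defaults: learning rate $10^{-3}$, batch 256)
on the mean binary cross-entropy.  One seed fixes initialisation, shuffling
and dropout, so a run is reproducible bit-for-bit.  The forward/backward
kernel is implemented in C++ (RcppArmadillo) and verified against central
finite differences to $10^{-4}$ relative error in the test suite; the
linear special case ($K=1$, identity MLP, empty adjacency) reduces exactly
to logistic regression on the flattened one-hot features and is tested
against `glm()`.

# The two-stage pipeline

`run_si_pipeline()` wires the stages:

1. stratified 80/20 split of the training cohort; quartile coder and edge
   matrices fitted on the training partition;
2. GIN-MaDE trained on the labeled subset; pseudo-labels ($\Pr \ge 0.5$,
   true labels never overwritten) fill the MaDE node for everyone;
3. three SI members trained on differently resampled training data;
4. soft voting: the ensemble score is exactly the arithmetic mean of the
   member sigmoid scores;
5. evaluation on the untouched external test cohort: sensitivity,
   specificity, accuracy, and AUC with a DeLong confidence interval.

## Resampling and the checkpoint rule

The balance ratio is the number of negatives per positive in the resampled
data.  Under-sampling keeps every positive and samples negatives without
replacement; SMOTE-NC adds synthetic positives interpolated between a
minority row and one of its $k=5$ nearest minority neighbours (Euclidean on
the ordinal/continuous features plus the SMOTE-NC nominal penalty — the
squared median of the continuous features' standard deviations per
differing nominal feature), rounding interpolated ordinals back to the
level grid and taking the neighbours' majority vote for nominal features.
Resampling happens on the tabular representation, before graph encoding,
and the edge matrix always comes from the original un-resampled training
partition, so synthetic rows never distort the population correlation
structure.

Each member keeps the checkpoint with minimal validation loss among epochs
whose validation sensitivity and specificity both exceed 80%; if no epoch
qualifies, the minimal-loss checkpoint is returned with a prominent
warning.  The member's validation fold is carved (stratified 80/20) from
its own resampled pool.  This matters: on a raw 1%-prevalence validation
fold, a member trained at ratio 5 is systematically over-confident, its
validation cross-entropy *rises* as it learns, and the min-loss rule would
select the untrained first epoch.  Measured at the member's own training
balance, loss falls as discrimination improves and the 80% constraint is
meaningful.  The external test set is never resampled.  The decision
threshold for the constraint defaults to 0.5 on the sigmoid score;
`checkpoint_rule(threshold = "youden")` instead uses, per epoch, the
validation threshold maximising sensitivity + specificity − 1, which is
useful when validating a member against data at a different prevalence
than it was trained on.

Because the three members see very different amounts of data per epoch
(roughly 1.5k under-sampled rows at ratio 10 versus ~32k SMOTE-NC rows, and
only a few hundred labeled rows for the MaDE model), the pipeline scales
epochs per stage (defaults: MaDE 400, ratio-10 member 40, ratio-5 member
60, SMOTE member = the config's epoch count) so each stage receives a
comparable number of optimisation updates.  The MaDE stage additionally
caps its batch size at 32: with one large batch per epoch the batch-norm
running statistics (momentum 0.1 per batch) lag far behind the weights,
and the model's inference-time scores stay saturated and miscalibrated
even when its ranking is already excellent — many small batches per epoch
keep the statistics current, and the pseudo-label binarization at 0.5
then behaves.

# Evaluation statistics

* **AUC** is the Mann–Whitney two-sample statistic (ties counted 1/2),
  computed via midranks; its variance is DeLong's structural-components
  estimator and the 95% CI a normal approximation clipped to [0, 1].  The
  test suite checks the AUC against exhaustive pair counting, the variance
  against a 10,000-replicate bootstrap (within 10%), and both against pROC.
* **Paired DeLong test** compares two correlated AUCs on the same subjects
  through the covariance of their structural components; identical score
  vectors give difference 0 and p = 1, and the test is antisymmetric.
* **Dependent-correlation comparison**: two Spearman correlations sharing a
  criterion (model score vs. criterion against PHQ_9 vs. criterion) are
  compared with Steiger's z on Fisher-transformed rank correlations with
  the inter-predictor correlation accounting for dependence; a
  subject-resampling bootstrap is the oracle in the tests.
* **Baselines**: penalized (lasso) logistic regression with
  cross-validated penalty, and a support-vector machine whose signed
  decision values pass through the logistic link — both consume the same
  flattened one-hot features the GIN sees, so the comparison isolates the
  model class.

# Attention plots

Saliency is the gradient of the **raw** (pre-sigmoid) output with respect
to every node-feature slot, averaged over a subject set and across ensemble
members.  Three display normalizations are provided: row-wise (each level
row scaled by its maximum absolute entry over the 19 ordinal nodes, signs
kept), column-wise (per binary node, min-max to [0, 1]), and L1-column (per
ordinal node, the L1 norm over its four level slots, scaled so the top node
is exactly 1).

Which subjects to average over is a real choice.  The default is the
positive subjects: with a ~1% outcome, the all-subject mean gradient is
dominated by the local model geometry around typical negative inputs, and
in the package's planted-signal experiments it systematically promotes the
highest-degree hub node (the state-anxiety total, which connects the whole
anxiety cluster) over the item that actually carries the planted effect.
Evaluated at case inputs, the gradient reflects what drives case scores,
and the planted item is recovered reliably.  `subjects = "all"` and
`subjects = "correct"` remain available.

Odds ratios for the binary items come from the plain 2×2 cross-tabulation
against acute SI, with the Haldane–Anscombe +0.5 correction (flagged) when
a cell is zero.

# The synthetic cohort generator

Real cohorts of this kind are not publicly distributable, so the package
ships a generator that emulates the statistical structure the method
assumes, and every end-to-end claim in the test suite is made against it.

* **Latent traits.** Four correlated Gaussian traits (depression, anxiety,
  resilience, self-esteem); defaults: depression–anxiety 0.6, resilience
  and self-esteem negatively correlated with anxiety (−0.5) and depression.
* **Items.** item = loading·trait + N(0,1), cut into 4 levels.  Default
  cutpoints are the item's own latent quartiles, so marginals are uniform
  and a zero loading yields exactly uniform levels.  Default loadings of
  1.6 (item–trait correlation ≈ 0.85) put within-scale inter-item
  correlations near 0.65–0.70 — high but within the range reported for
  short depression/anxiety screeners — which is what lets the edge matrix
  retain within-scale edges at the 0.6 threshold; with weak loadings the
  graph would be empty and every ordinal node exchangeable under
  sum-pooling.
* **Totals.** Integer totals for state anxiety, resilience and self-esteem
  generated from their traits with realistic means, spreads and ranges.
* **Outcomes.** Logistic models on the traits (and, for acute SI, on
  lifetime SA, MaDE, gender, institution), with intercepts calibrated by
  bisection on [−20, 20] to hit target prevalences (defaults: acute SI 1%,
  lifetime SA 1.4%, MaDE 10% with 1.1% of subjects labeled) to within
  1e-6.
* **The planted top item.** Acute SI additionally receives a direct
  coefficient (0.8) on the standardized latent anhedonia item (PHQ_2),
  whose loading (2.2) is also the largest.  A trait-level coefficient
  alone cannot make one *item* the strongest single-item effect — the
  effect would be shared by every item loading on the trait — and the
  direct anhedonia–SI association beyond depression is itself a documented
  clinical finding.  With these defaults the model-free association
  oracle (Spearman of node code with the SI linear predictor) puts PHQ_2
  first by a clear margin (≈0.87 vs ≈0.76 for its siblings), so recovery
  experiments have an unambiguous ground truth.
* **Criterion scale.** A non-negative integer suicide-ideation scale score
  is observed for a 6% subset, generated as a noisy monotone function of
  the SI linear predictor; it serves as the external criterion for the
  label-validity correlation analyses.

What the generator does *not* emulate: multi-center distribution shift
(the study's training and external test centers differ in prevalence and
demographics; the generator draws both cohorts from one population, with
the spec's optional shift emulation left off), item-level missingness,
response styles (acquiescence, social desirability), and any non-Gaussian
dependence beyond the single-factor-per-scale structure.  Passing the
recovery experiments therefore shows the pipeline recovers planted effects
under the method's own assumptions — not that it transfers across shifted
centers.

# Scale of the shipped experiments

The recovery experiments run at 20,000 training subjects (1% prevalence,
so ~200 positives), an 8,000-subject external test cohort, and a compact
architecture (3 layers, width 16, the per-stage epoch counts above) chosen
so a full two-stage run completes in about a minute on one core while
leaving all qualitative behaviours intact: members and ensemble clear AUC
0.8 comfortably, the resampled members' sensitivity at threshold 0.5
dwarfs the raw-imbalance member's, and the planted item tops the saliency
ranking.  The architecture defaults in `gin_config()` (5 layers, width 64)
mirror the full-scale configuration and remain the package defaults for
real use.

# Numerical choices and degenerate inputs

* Sigmoid scores are clipped to [1e-7, 1−1e-7] inside the loss.
* Constant node columns correlate with nothing: their edges are zeroed
  with a warning.  Constant total-score columns make the quartile coder
  degenerate and raise an error.
* Quartile coding clamps unseen extremes into levels 1/4.
* AUC requires both classes; with single-class labels sensitivity or
  specificity is reported as `NA`, never as 0.
* Identical score vectors in the paired DeLong test give difference 0 and
  p = 1; perfectly dependent predictors in the Steiger comparison give
  z = 0.
* Under-sampling clamps to the available negatives (with a warning) when
  the requested ratio exceeds them; SMOTE-NC requires at least k+1
  minority rows.
* All stage seeds derive from one master seed through a fixed documented
  rule (`stage_seed()`), and two runs with the same master seed agree on
  every score bit-for-bit.

# Known limitations

* Gradient saliency on near-exchangeable items compresses effect-size
  differences; rankings among statistically similar items (the
  non-planted PHQ items, say) should not be over-interpreted.
* The pseudo-label stage inherits the MaDE model's biases; with only ~220
  labeled subjects its accuracy depends on the separability of the
  diagnosis in item space.
* The checkpoint constraint (both validation rates above 80%) may be
  unattainable for a weak member; the fallback (minimal loss, loud
  warning) is deliberate and visible rather than silent.
* DeLong's normal approximation is anti-conservative for AUCs very close
  to 1 at small n; the CI is clipped to [0, 1] but no exact method is
  provided.
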