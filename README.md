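# ginscreen

Graph-neural-network screening of **acute suicidal ideation** (SI within
the past two weeks, a ~1%-prevalence outcome) from multi-dimensional
mental-health questionnaires, for researchers building or auditing
survey-based suicide-risk screens.

Each subject's questionnaire responses become a small graph: 19 ordinal
nodes (PHQ-9 depression items, GAD-7 anxiety items, quartile-coded state
anxiety / resilience / self-esteem totals) plus binary
clinico-demographic nodes (lifetime suicide attempt, major depressive
episode, gender, institution type), with one-hot level features and a
**shared sparse correlation edge matrix** (pairwise Spearman correlations
between node codes, thresholded at |ρ| ≥ 0.6, signs kept).  A **graph
isomorphism network** classifies the graphs,

    h_v^(k) = MLP_k( (1 + ε_k) h_v^(k−1) + Σ_u A[v,u] h_u^(k−1) ),

with per-layer sum-pooling, a concatenated readout and a sigmoid score.
Class imbalance is handled by an ensemble of three GINs trained on
differently rebalanced data — under-sampling to balance ratios 10 and 5,
and SMOTE-NC over-sampling to ratio 1 — combined by **soft voting** (the
arithmetic mean of the member sigmoid scores).  The sparsely observed
major-depressive-episode diagnosis is **pseudo-labeled** by a GIN trained
on the labeled subset and fed back as an input node.  Fitted ensembles are
interpreted with **gradient attention plots** (∂y/∂x of the raw score per
node and level, with row-wise, column-wise and L1-column normalizations)
and odds ratios for the binary items.  Evaluation includes DeLong AUC
confidence intervals and paired tests, Steiger comparisons of dependent
rank correlations, and lasso-logistic / SVM baselines on identical
features.

Because cohorts of this kind cannot be redistributed, the package ships a
**synthetic cohort generator** (correlated ordinal items from latent
depression/anxiety/resilience/self-esteem traits, calibrated rare
outcomes, partial label availability, and a planted top-effect item) so
the entire pipeline is testable end-to-end; see the methods vignette
(`vignettes/ginscreen-methods.Rmd`) for the model and every design
decision.

## Worked example

```r
library(ginscreen)

train <- generate_cohort(n = 20000, seed = stage_seed(1, "cohort"))
test  <- generate_cohort(n = 8000,  seed = stage_seed(1, "cohort_test"))
summarize_cohort(train$cohort)
#> Cohort summary (n = 20000)
#>   acute_SI                  224 (1.12%)
#>   lifetime_SA               291 (1.46%)
#>   MaDE_labeled_positive      25 (0.13%)

fit <- run_si_pipeline(train$cohort, test$cohort,
                       config = gin_config(n_layers = 3, width = 16,
                                           epochs = 10),
                       master_seed = 1)
fit
#> Acute-SI GIN ensemble (seed 1)
#>   external test: n = 8000 (91 positive)
#>   sensitivity 0.846  specificity 0.844  accuracy 0.844
#>   AUC 0.922 (95% CI 0.889-0.955)

att <- population_attention(fit$ensemble, fit$test_graphs)
sort(normalize_attention(att, "l1-column")[1, ], decreasing = TRUE)[1:3]
#>     PHQ_2     PHQ_3     PHQ_6
#> 1.0000000 0.9454981 0.9440933
```

The summary lines are the cohort's outcome counts with percentages as
screening studies print them.  The pipeline report gives the soft-voting
ensemble's external-test operating point at threshold 0.5 — the balanced
sensitivity/specificity that imbalance-naive models fail to reach at 1%
prevalence — and its AUC with a DeLong 95% confidence interval.  The
L1-column attention ranking recovers the planted strongest item
(anhedonia, PHQ_2) at the top.

(Small architecture and epoch counts keep the example quick; defaults in
`gin_config()` are 5 layers and width 64.)

## Command line

A staged CLI covering simulate → train-made → pseudo-label → build-graph
→ train-si → evaluate / ablate / attention / compare ships in
`inst/cli/ginscreen.R`:

```sh
Rscript inst/cli/ginscreen.R simulate  --config run.yaml --out out/
Rscript inst/cli/ginscreen.R train-made --config run.yaml --out out/
...
```

Every command logs to `out/run_log.jsonl` and stamps artifacts with the
config hash; mixing artifacts from different configs is refused.

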